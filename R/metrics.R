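# Clustering-agreement and network-quality metric suite. Every metric here
# is validated in the tests against an independent brute-force
# implementation on small instances.

#' Adjusted Rand index
#'
#' Hubert-Arabie pair-counting ARI between two labelings of the same items;
#' 1 for identical partitions, expectation ~0 under random labelings, can
#' be negative.
#'
#' @param labels_a,labels_b vectors over the same items (named vectors are
#'   matched by name).
#' @return scalar in [-1, 1].
#' @export
ari <- function(labels_a, labels_b) {
  if (!is.null(names(labels_a)) && !is.null(names(labels_b))) {
    if (!setequal(names(labels_a), names(labels_b)))
      stop("ari: label supports differ")
    labels_b <- labels_b[names(labels_a)]
  }
  if (length(labels_a) != length(labels_b))
    stop("ari: label supports differ")
  n <- length(labels_a)
  if (n < 2) stop("ari: need at least 2 items")
  tab <- table(labels_a, labels_b)
  choose2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(choose2(tab))
  a <- sum(choose2(rowSums(tab)))
  b <- sum(choose2(colSums(tab)))
  nc2 <- choose2(n)
  expected <- a * b / nc2
  mx <- (a + b) / 2
  if (mx == expected) return(1)    # both partitions trivial and identical
  (sum_ij - expected) / (mx - expected)
}

#' Average silhouette width
#'
#' Per cell, \code{sil = (n - m) / max(m, n)} with m the mean distance to
#' its own cluster's other members and n the mean distance to the nearest
#' other cluster; the ASW is the mean over cells.
#'
#' @param x embedding matrix (rows = cells) or a \code{dist} /
#'   distance matrix.
#' @param labels cluster ids per cell.
#' @return scalar in [-1, 1].
#' @export
asw <- function(x, labels) {
  D <- if (inherits(x, "dist")) as.matrix(x)
       else if (is.matrix(x) && isSymmetric(unname(x)) &&
                all(diag(x) == 0) && nrow(x) == length(labels) &&
                ncol(x) == length(labels)) x
       else as.matrix(stats::dist(x))
  labels <- as.vector(labels)
  ks <- unique(labels)
  if (length(ks) < 2) stop("asw: need at least 2 clusters")
  n <- length(labels)
  sil <- numeric(n)
  for (j in seq_len(n)) {
    own <- which(labels == labels[j])
    m <- if (length(own) > 1) mean(D[j, setdiff(own, j)]) else 0
    nn <- min(vapply(setdiff(ks, labels[j]), function(k) {
      mean(D[j, labels == k])
    }, numeric(1)))
    sil[j] <- if (length(own) == 1) 0 else (nn - m) / max(m, nn)
  }
  mean(sil)
}

#' Calinski-Harabasz index
#'
#' \code{CH = [tr(B_k) / tr(W_k)] * (n - k) / (k - 1)} with W_k the
#' within-cluster and B_k the between-cluster scatter about the centroids;
#' tr(W_k) + tr(B_k) equals the total scatter about the grand centroid.
#'
#' @param x embedding matrix (rows = points).
#' @param labels cluster ids.
#' @return scalar (larger = better separated).
#' @export
calinski_harabasz <- function(x, labels) {
  x <- as.matrix(x)
  ks <- unique(labels)
  k <- length(ks); n <- nrow(x)
  if (k < 2 || n <= k) stop("calinski_harabasz: need 2 <= k < n")
  grand <- colMeans(x)
  trW <- 0; trB <- 0
  for (cl in ks) {
    pts <- x[labels == cl, , drop = FALSE]
    if (nrow(pts) == 0) stop("calinski_harabasz: empty cluster")
    ctr <- colMeans(pts)
    trW <- trW + sum(sweep(pts, 2, ctr)^2)
    trB <- trB + nrow(pts) * sum((ctr - grand)^2)
  }
  (trB / trW) * (n - k) / (k - 1)
}

#' Davies-Bouldin index
#'
#' \code{DB = (1/k) sum_i max_{j != i} (s_i + s_j) / d_ij} with s the mean
#' distance of cluster members to their centroid and d_ij the centroid
#' distance. Lower is better; coincident centroids give an infinite ratio
#' with a warning.
#'
#' @param x embedding matrix.
#' @param labels cluster ids.
#' @return scalar >= 0.
#' @export
davies_bouldin <- function(x, labels) {
  x <- as.matrix(x)
  ks <- unique(labels)
  k <- length(ks)
  if (k < 2) stop("davies_bouldin: need at least 2 clusters")
  ctr <- t(vapply(ks, function(cl) colMeans(x[labels == cl, , drop = FALSE]),
                  numeric(ncol(x))))
  s <- vapply(seq_along(ks), function(i) {
    pts <- x[labels == ks[i], , drop = FALSE]
    mean(sqrt(rowSums(sweep(pts, 2, ctr[i, ])^2)))
  }, numeric(1))
  dctr <- as.matrix(stats::dist(ctr))
  if (any(dctr[upper.tri(dctr)] == 0))
    warning("davies_bouldin: coincident centroids, index is infinite")
  R <- outer(s, s, "+") / dctr
  diag(R) <- -Inf
  mean(apply(R, 1, max))
}

#' Closeness centrality of a weighted undirected graph
#'
#' \code{CC(u) = 1 / sum_v d_w(u, v)} over shortest weighted paths; for an
#' unreachable v the total number of vertices is substituted for the path
#' length. A single-node graph has CC 0. The network-level score is the
#' mean over nodes.
#'
#' @param graph an \pkg{igraph} graph, or an edge data.frame (from, to,
#'   weight).
#' @return list: per-node \code{scores}, \code{network} mean.
#' @export
closeness_centrality <- function(graph) {
  g <- as_metric_graph(graph)
  n <- igraph::vcount(g)
  if (n == 0) stop("closeness_centrality: empty graph")
  if (n == 1)
    return(list(scores = stats::setNames(0, igraph::V(g)$name), network = 0))
  D <- igraph::distances(g, weights = igraph::E(g)$weight)
  D[is.infinite(D)] <- n
  tot <- rowSums(D)
  scores <- 1 / tot
  list(scores = scores, network = mean(scores))
}

#' Eigenvector centrality of a weighted undirected graph
#'
#' Scores are the entries of the principal eigenvector of the non-negative
#' weighted adjacency matrix (computed per connected component), taken
#' non-negative and normalized to unit maximum. The network-level score is
#' the mean over nodes.
#'
#' @param graph an \pkg{igraph} graph or edge data.frame.
#' @return list: per-node \code{scores}, \code{network} mean.
#' @export
eigenvector_centrality <- function(graph) {
  g <- as_metric_graph(graph)
  if (igraph::vcount(g) == 0) stop("eigenvector_centrality: empty graph")
  A <- as.matrix(igraph::as_adjacency_matrix(g, attr = "weight",
                                             sparse = TRUE))
  scores <- eigenvector_centrality_matrix(A)
  list(scores = scores, network = mean(scores))
}

# principal eigenvector per connected component, non-negative, global unit
# maximum; components ranked by their Perron eigenvalue
eigenvector_centrality_matrix <- function(A) {
  stopifnot(isSymmetric(unname(A)), all(A >= 0))
  n <- nrow(A)
  comp <- igraph::components(
    igraph::graph_from_adjacency_matrix(A > 0, mode = "undirected"))
  scores <- numeric(n)
  lambda <- numeric(comp$no)
  for (c0 in seq_len(comp$no)) {
    ix <- which(comp$membership == c0)
    if (length(ix) == 1) { scores[ix] <- 0; next }
    e <- eigen(A[ix, ix, drop = FALSE], symmetric = TRUE)
    v <- e$vectors[, 1]
    if (sum(v) < 0) v <- -v
    scores[ix] <- pmax(v, 0)
    lambda[c0] <- e$values[1]
  }
  if (max(scores) > 0) {
    # scale components relative to the dominant one, as a single spectrum
    top <- which.max(lambda)
    for (c0 in seq_len(comp$no)) {
      ix <- which(comp$membership == c0)
      if (max(scores[ix]) > 0 && lambda[top] > 0)
        scores[ix] <- scores[ix] / max(scores[ix]) *
          (lambda[c0] / lambda[top])
    }
    scores <- scores / max(scores)
  }
  stats::setNames(scores, rownames(A))
}

as_metric_graph <- function(graph) {
  if (igraph::is_igraph(graph)) {
    if (is.null(igraph::E(graph)$weight)) igraph::E(graph)$weight <- 1
    return(graph)
  }
  stopifnot(is.data.frame(graph))
  if (is.null(graph$weight)) graph$weight <- 1
  igraph::graph_from_data_frame(graph, directed = FALSE)
}

#' Match predicted cluster ids to reference labels by majority overlap
#'
#' @param predicted a \code{cluster_labeling} or named vector of cluster
#'   ids.
#' @param reference named vector of reference labels over the same cells.
#' @return named vector: predicted cluster id (as name) -> reference label
#'   with the largest overlap.
#' @export
match_clusters <- function(predicted, reference) {
  if (inherits(predicted, "cluster_labeling"))
    predicted <- predicted$assignment
  cells <- intersect(names(predicted), names(reference))
  tab <- table(predicted[cells], reference[cells])
  stats::setNames(as.integer(colnames(tab)[apply(tab, 1, which.max)]),
                  rownames(tab))
}

#' Evaluate a clustering (and optionally a network) with the full metric
#' suite
#'
#' @param embedding cells x d matrix.
#' @param labels predicted labels (named by barcode).
#' @param benchmark optional reference labels for ARI.
#' @param network optional edge data.frame for centrality scores.
#' @return named list of metric values.
#' @export
evaluate_metrics <- function(embedding, labels, benchmark = NULL,
                             network = NULL) {
  out <- list(
    asw = asw(embedding, labels),
    calinski_harabasz = calinski_harabasz(embedding, labels),
    davies_bouldin = davies_bouldin(embedding, labels))
  if (!is.null(benchmark)) out$ari <- ari(labels, benchmark)
  if (!is.null(network) && nrow(network) > 0) {
    out$closeness <- closeness_centrality(network)$network
    out$eigenvector <- eigenvector_centrality(network)$network
  }
  out
}
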