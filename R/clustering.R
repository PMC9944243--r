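#' Shared-nearest-neighbor graph on cell embeddings
#'
#' k nearest neighbors under Euclidean distance, re-weighted by the Jaccard
#' overlap of neighbor sets (each node counted in its own neighborhood) and
#' pruned below \code{prune}; the result is a symmetric weighted
#' \pkg{igraph} graph.
#'
#' @param cell_emb cells x d embedding matrix (rownames = barcodes).
#' @param k neighbors (default 20).
#' @param prune minimum Jaccard weight kept (default 1/15).
#' @return an \pkg{igraph} graph with vertex names = barcodes.
#' @export
knn_graph <- function(cell_emb, k = 20, prune = 1 / 15) {
  n <- nrow(cell_emb)
  if (k >= n) stop("knn_graph: k must be smaller than the number of cells")
  D <- as.matrix(stats::dist(cell_emb))
  nbr <- matrix(0L, n, k + 1)
  for (i in seq_len(n)) nbr[i, ] <- order(D[i, ])[seq_len(k + 1)]
  # adjacency of neighborhood membership (self included)
  A <- Matrix::sparseMatrix(i = rep(seq_len(n), k + 1), j = as.vector(nbr),
                            x = 1, dims = c(n, n))
  shared <- Matrix::tcrossprod(A)              # |N(i) intersect N(j)|
  shared <- as.matrix(shared)
  jac <- shared / (2 * (k + 1) - shared)
  jac[jac < prune] <- 0
  diag(jac) <- 0
  g <- igraph::graph_from_adjacency_matrix(jac, mode = "max",
                                           weighted = TRUE)
  igraph::V(g)$name <- rownames(cell_emb)
  g
}

#' Louvain (or Leiden) clustering of the cell graph
#'
#' Modularity-optimizing community detection at the given resolution;
#' cluster ids are renumbered by decreasing size so the labeling is
#' reproducible. Seed-deterministic.
#'
#' @param graph \pkg{igraph} graph from [knn_graph()].
#' @param resolution clustering resolution (default 0.4).
#' @param seed RNG seed.
#' @param method \code{"louvain"} (default) or \code{"leiden"}.
#' @return a \code{cluster_labeling}: named integer \code{assignment}
#'   (barcode -> cluster in 1..Z), \code{Z}, \code{resolution}.
#' @export
louvain_cluster <- function(graph, resolution = 0.4, seed = 1,
                            method = c("louvain", "leiden")) {
  method <- match.arg(method)
  set.seed(seed)
  com <- if (method == "louvain") {
    igraph::cluster_louvain(graph, resolution = resolution)
  } else {
    igraph::cluster_leiden(graph, objective_function = "modularity",
                           resolution = resolution, n_iterations = 5)
  }
  memb <- igraph::membership(com)
  sizes <- sort(table(memb), decreasing = TRUE)
  relab <- stats::setNames(seq_along(sizes), names(sizes))
  assignment <- stats::setNames(as.integer(relab[as.character(memb)]),
                                igraph::V(graph)$name)
  structure(list(assignment = assignment, Z = length(sizes),
                 resolution = resolution),
            class = "cluster_labeling")
}

#' @export
print.cluster_labeling <- function(x, ...) {
  cat(sprintf("<cluster_labeling> %d cells in %d clusters (resolution %g)\n",
              length(x$assignment), x$Z, x$resolution))
  print(table(cluster = x$assignment))
  invisible(x)
}

#' Cells belonging to one cluster
#'
#' @param labels a \code{cluster_labeling}.
#' @param z cluster id.
#' @return character vector of barcodes.
#' @export
cluster_cells <- function(labels, z) {
  names(labels$assignment)[labels$assignment == z]
}

#' Remove one cell cluster from aligned matrices (leave-out protocol)
#'
#' Drops all cells of cluster \code{z} from every supplied matrix and
#' re-indexes the remaining cluster labels contiguously (by decreasing
#' size).
#'
#' @param matrices named list of \code{named_matrix} /
#'   \code{integrated_matrix} objects (columns = cells).
#' @param labels a \code{cluster_labeling} covering those cells.
#' @param z cluster id to remove.
#' @return list: \code{matrices} (reduced), \code{labels} (re-indexed
#'   \code{cluster_labeling}).
#' @export
leave_out_cluster <- function(matrices, labels, z) {
  if (!z %in% labels$assignment) stop("leave_out_cluster: no such cluster")
  drop_cells <- cluster_cells(labels, z)
  keep <- setdiff(names(labels$assignment), drop_cells)
  if (length(keep) == 0) stop("leave_out_cluster: removal empties the data")
  red <- lapply(matrices, function(m) {
    cols <- intersect(colnames(m$values), keep)
    m$values <- m$values[, cols, drop = FALSE]
    m
  })
  rest <- labels$assignment[keep]
  sizes <- sort(table(rest), decreasing = TRUE)
  relab <- stats::setNames(seq_along(sizes), names(sizes))
  new_lab <- structure(list(
    assignment = stats::setNames(as.integer(relab[as.character(rest)]), keep),
    Z = length(sizes), resolution = labels$resolution),
    class = "cluster_labeling")
  list(matrices = red, labels = new_lab)
}
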