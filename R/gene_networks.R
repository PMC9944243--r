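# Cell-cluster-active gene association networks: an augmented gene-gene /
# gene-cell graph filtered by embedding correlation and attention, connected
# per cluster by an (approximate) Steiner forest over the cluster's cells.

#' Build the augmented gene graph for one cell cluster
#'
#' Gene-cell edges carry the attention scores a_ij restricted to cells of
#' cluster z, kept when a_ij > mean + sd of the attention values incident to
#' those cells (strict inequality; \code{threshold_scope = "per_cell"}
#' computes the statistic per cell instead). Gene-gene edges carry the
#' Pearson correlation of HGT gene embeddings among the genes passing the
#' attention filter (all genes with \code{full_gene_graph = TRUE}), kept when
#' correlation > 0.5. Surviving weights are max-min inverted per graph so
#' the largest original weight maps to cost 0 and the smallest to cost 1.
#'
#' @param gene_emb genes x d HGT gene embedding matrix.
#' @param attention sparse genes x cells attention matrix.
#' @param labels a \code{cluster_labeling}.
#' @param z cluster id.
#' @param cor_threshold gene-gene correlation threshold (default 0.5).
#' @param threshold_scope \code{"per_cluster"} (default) or
#'   \code{"per_cell"}.
#' @param full_gene_graph consider all gene pairs, not only attention-passing
#'   genes (default FALSE).
#' @return an \code{augmented_graph}: \pkg{igraph} graph with vertex
#'   attribute \code{type} (gene/cell), edge attributes \code{weight}
#'   (inverted-normalized cost), \code{orig_weight}, \code{kind}
#'   (gene_gene/gene_cell); plus the attention threshold used.
#' @export
build_augmented_graph <- function(gene_emb, attention, labels, z,
                                  cor_threshold = 0.5,
                                  threshold_scope = c("per_cluster",
                                                      "per_cell"),
                                  full_gene_graph = FALSE) {
  threshold_scope <- match.arg(threshold_scope)
  cells <- cluster_cells(labels, z)
  A <- attention[, cells, drop = FALSE]
  As <- Matrix::summary(A)
  gc_edges <- data.frame(gene = rownames(A)[As$i], cell = cells[As$j],
                         a = As$x, stringsAsFactors = FALSE)
  gc_edges <- gc_edges[gc_edges$a > 0, , drop = FALSE]
  if (threshold_scope == "per_cluster") {
    thr <- mean(gc_edges$a) + stats::sd(gc_edges$a)
    if (is.na(thr)) thr <- Inf
    keep <- gc_edges$a > thr
  } else {
    thr <- stats::ave(gc_edges$a, gc_edges$cell,
                      FUN = function(x) mean(x) + stats::sd(x))
    thr[is.na(thr)] <- Inf
    keep <- gc_edges$a > thr
    thr <- NA_real_
  }
  gc_edges <- gc_edges[keep, , drop = FALSE]
  if (nrow(gc_edges) == 0)
    stop(sprintf(paste0("build_augmented_graph: no gene-cell edge survives",
                        " the attention threshold (%.4g) for cluster %d"),
                 if (is.na(thr)) NaN else thr, z))
  cand_genes <- if (full_gene_graph) rownames(gene_emb)
                else unique(gc_edges$gene)
  gg_edges <- data.frame(g1 = character(), g2 = character(), r = numeric())
  if (length(cand_genes) >= 2) {
    cm <- stats::cor(t(gene_emb[cand_genes, , drop = FALSE]))
    cm[is.na(cm)] <- 0
    idx <- which(upper.tri(cm) & cm > cor_threshold, arr.ind = TRUE)
    if (nrow(idx))
      gg_edges <- data.frame(g1 = cand_genes[idx[, 1]],
                             g2 = cand_genes[idx[, 2]],
                             r = cm[idx], stringsAsFactors = FALSE)
  }
  # inverted max-min normalization, applied within each edge type: the
  # largest weight maps to cost 0 and the smallest to 1. Correlations
  # (~0.5-1) and attention scores (~1e-2) live on different scales; a joint
  # normalization would price every attention edge near 1 regardless of its
  # rank and collapse the Steiner forest onto single hub genes.
  inv <- function(w) {
    rng <- range(w)
    if (rng[2] > rng[1]) (rng[2] - w) / (rng[2] - rng[1])
    else rep(0, length(w))
  }
  genes <- unique(c(gg_edges$g1, gg_edges$g2, gc_edges$gene))
  used_cells <- unique(gc_edges$cell)
  el <- rbind(
    if (nrow(gg_edges))
      data.frame(from = gg_edges$g1, to = gg_edges$g2,
                 weight = inv(gg_edges$r), orig_weight = gg_edges$r,
                 kind = "gene_gene"),
    data.frame(from = gc_edges$gene, to = gc_edges$cell,
               weight = inv(gc_edges$a), orig_weight = gc_edges$a,
               kind = "gene_cell"))
  vdf <- data.frame(name = c(genes, used_cells),
                    type = c(rep("gene", length(genes)),
                             rep("cell", length(used_cells))))
  g <- igraph::graph_from_data_frame(el, directed = FALSE, vertices = vdf)
  structure(list(graph = g, cluster = z, attention_threshold = thr,
                 terminals = intersect(cells, used_cells),
                 unreachable_cells = setdiff(cells, used_cells)),
            class = "augmented_graph")
}

#' @export
print.augmented_graph <- function(x, ...) {
  ty <- igraph::V(x$graph)$type
  cat(sprintf(paste0("<augmented_graph> cluster %d: %d genes, %d cells,",
                     " %d edges (%d unreachable cells)\n"),
              x$cluster, sum(ty == "gene"), sum(ty == "cell"),
              igraph::ecount(x$graph), length(x$unreachable_cells)))
  invisible(x)
}

# shortest alternating-path distances between terminals: a terminal-terminal
# path is cell - gene - (gene path) - gene - cell, with no intermediate cell
# nodes, so distances decompose through the gene-only subgraph.
terminal_distances <- function(ag) {
  g <- ag$graph
  ty <- igraph::V(g)$type
  gene_v <- which(ty == "gene")
  gsub <- igraph::induced_subgraph(g, gene_v)
  Dg <- igraph::distances(gsub, weights = igraph::E(gsub)$weight)
  terms <- ag$terminals
  # cost of the entry edge cell -> gene (Inf when absent)
  C <- matrix(Inf, length(terms), length(gene_v),
              dimnames = list(terms, igraph::V(gsub)$name))
  for (ti in seq_along(terms)) {
    inc <- igraph::incident(g, terms[ti])
    ends <- igraph::ends(g, inc)
    other <- ifelse(ends[, 1] == terms[ti], ends[, 2], ends[, 1])
    C[ti, other] <- igraph::E(g)$weight[as.integer(inc)]
  }
  # M[t, b] = min_a C[t, a] + Dg[a, b]
  M <- apply(C, 1, function(ct) {
    apply(Dg + ct, 2, min)
  })
  # apply drops dimensions for a single gene; keep terms x genes shape
  M <- matrix(M, nrow = ncol(C), ncol = length(terms))
  M <- t(M)
  D <- matrix(Inf, length(terms), length(terms),
              dimnames = list(terms, terms))
  for (i in seq_along(terms))
    for (j in seq_along(terms))
      if (i < j) D[i, j] <- D[j, i] <- min(M[i, ] + C[j, ])
  diag(D) <- 0
  list(D = D, C = C, Dg = Dg, gsub = gsub)
}

#' Approximate Steiner forest over a cluster's cells
#'
#' Terminals are the cluster's cells; paths must enter and leave through
#' gene-cell edges and run through genes internally. The solver is the
#' classical shortest-path 2-approximation: build the terminal metric
#' closure from alternating-path distances, take its minimum spanning tree
#' per connected terminal component, expand tree edges back into graph
#' paths, and prune degree-1 non-terminal nodes. Terminals with no incident
#' surviving edge are reported unreachable and excluded with a warning.
#'
#' @param ag an \code{augmented_graph}.
#' @return an \code{sfp_solution}: edge data.frame (from, to, weight,
#'   orig_weight, kind), \code{steiner_genes}, \code{terminals} used,
#'   \code{cost} (summed normalized weight).
#' @export
solve_sfp <- function(ag) {
  if (length(ag$unreachable_cells))
    warning("solve_sfp: ", length(ag$unreachable_cells),
            " terminal(s) with no surviving edge excluded")
  terms <- ag$terminals
  g <- ag$graph
  empty <- data.frame(from = character(), to = character(),
                      weight = numeric(), orig_weight = numeric(),
                      kind = character())
  if (length(terms) <= 1) {
    # a single cell needs no connecting forest
    return(structure(list(edges = empty, steiner_genes = character(),
                          terminals = terms, cost = 0),
                     class = "sfp_solution"))
  }
  td <- terminal_distances(ag)
  D <- td$D
  comp_of <- rep(NA_integer_, length(terms))
  finD <- is.finite(D)
  comp_graph <- igraph::graph_from_adjacency_matrix(finD, mode = "undirected",
                                                    diag = FALSE)
  comp_of <- igraph::components(comp_graph)$membership
  sel_edges <- character(0)
  gene_names <- colnames(td$C)
  edge_ids <- integer(0)
  expand_pair <- function(t1, t2) {
    # recover argmin genes a (entry of t1) and b (entry of t2)
    scores <- outer(td$C[t1, ], td$C[t2, ], "+") + td$Dg
    ab <- which(scores == min(scores), arr.ind = TRUE)[1, ]
    a <- gene_names[ab[1]]; b <- gene_names[ab[2]]
    ids <- c(igraph::get_edge_ids(g, c(terms[t1], a)),
             igraph::get_edge_ids(g, c(terms[t2], b)))
    if (a != b) {
      sp <- igraph::shortest_paths(td$gsub, from = a, to = b,
                                   weights = igraph::E(td$gsub)$weight,
                                   output = "epath")$epath[[1]]
      ends <- igraph::ends(td$gsub, sp)
      for (r in seq_len(nrow(ends)))
        ids <- c(ids, igraph::get_edge_ids(g, c(ends[r, 1], ends[r, 2])))
    }
    ids
  }
  for (cmp in unique(comp_of)) {
    members <- which(comp_of == cmp)
    if (length(members) < 2) next
    sub <- D[members, members, drop = FALSE]
    mg <- igraph::graph_from_adjacency_matrix(sub, mode = "undirected",
                                              weighted = TRUE, diag = FALSE)
    mst <- igraph::mst(mg, weights = igraph::E(mg)$weight)
    me <- igraph::ends(mst, igraph::E(mst))
    for (r in seq_len(nrow(me))) {
      t1 <- match(me[r, 1], terms); t2 <- match(me[r, 2], terms)
      edge_ids <- c(edge_ids, expand_pair(t1, t2))
    }
  }
  edge_ids <- unique(edge_ids[edge_ids > 0])
  if (!length(edge_ids))
    return(structure(list(edges = empty, steiner_genes = character(),
                          terminals = terms, cost = 0),
                     class = "sfp_solution"))
  sol <- igraph::subgraph_from_edges(g, edge_ids)
  # prune degree-1 non-terminal (gene) leaves
  repeat {
    deg <- igraph::degree(sol)
    drop <- names(deg)[deg <= 1 & !(names(deg) %in% terms) &
                         igraph::V(sol)$type == "gene"]
    if (!length(drop)) break
    sol <- igraph::delete_vertices(sol, drop)
  }
  ed <- igraph::as_data_frame(sol, what = "edges")
  structure(list(edges = ed[, c("from", "to", "weight", "orig_weight",
                                "kind")],
                 steiner_genes = igraph::V(sol)$name[
                   igraph::V(sol)$type == "gene"],
                 terminals = terms, cost = sum(ed$weight)),
            class = "sfp_solution")
}

#' @export
print.sfp_solution <- function(x, ...) {
  cat(sprintf(paste0("<sfp_solution> %d terminals, %d Steiner genes,",
                     " %d edges, cost %.4g\n"),
              length(x$terminals), length(x$steiner_genes),
              nrow(x$edges), x$cost))
  invisible(x)
}

#' Extract the cluster-active gene association network
#'
#' The gene-gene edges of the Steiner forest with their original
#' (un-inverted) correlation weights; each gene is annotated with its total
#' attention to the cluster's cells.
#'
#' @param solution an \code{sfp_solution}.
#' @param ag the \code{augmented_graph} it was solved on.
#' @param attention sparse genes x cells attention matrix.
#' @param labels,z cluster labeling and cluster id.
#' @return a \code{gene_network}: \code{edges} (gene1, gene2, weight),
#'   \code{genes} data.frame (gene, attention_sum), \code{cluster}.
#' @export
extract_network <- function(solution, ag, attention, labels, z) {
  gg <- solution$edges[solution$edges$kind == "gene_gene", , drop = FALSE]
  genes <- solution$steiner_genes
  cells <- cluster_cells(labels, z)
  att_sum <- if (length(genes))
    Matrix::rowSums(attention[genes, intersect(cells, colnames(attention)),
                              drop = FALSE]) else numeric(0)
  structure(list(
    edges = data.frame(gene1 = gg$from, gene2 = gg$to,
                       weight = gg$orig_weight, stringsAsFactors = FALSE),
    genes = data.frame(gene = genes, attention_sum = as.numeric(att_sum),
                       stringsAsFactors = FALSE),
    cluster = z), class = "gene_network")
}

#' @export
print.gene_network <- function(x, ...) {
  cat(sprintf("<gene_network> cluster %d: %d genes, %d gene-gene edges\n",
              x$cluster, nrow(x$genes), nrow(x$edges)))
  invisible(x)
}

#' Exhaustive Steiner-forest optimum on a small augmented graph
#'
#' Brute-force reference: enumerates all edge subsets (graphs with at most
#' ~16 edges) and returns the minimum total weight subset connecting every
#' terminal pair that the full graph connects, under the same alternating
#' path rule (no intermediate cell nodes). Used to validate the
#' 2-approximation.
#'
#' @param ag an \code{augmented_graph}.
#' @return list \code{cost}, \code{edges} (indices into E(ag$graph)).
#' @export
sfp_bruteforce <- function(ag) {
  g <- ag$graph
  E <- igraph::ecount(g)
  if (E > 16) stop("sfp_bruteforce: too many edges")
  terms <- ag$terminals
  w <- igraph::E(g)$weight
  ends <- igraph::ends(g, igraph::E(g))
  ty <- stats::setNames(igraph::V(g)$type, igraph::V(g)$name)
  genes <- names(ty)[ty == "gene"]
  gid <- stats::setNames(seq_along(genes), genes)
  is_gg <- ty[ends[, 1]] == "gene" & ty[ends[, 2]] == "gene"
  # feasible(ids): terminal pairs connected via gene-internal paths, using
  # union-find over gene components plus one gene-cell hop at each end
  pair_feasible <- function(ids) {
    parent <- seq_along(genes)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    for (e in ids[is_gg[ids]]) {
      a <- find(gid[ends[e, 1]]); b <- find(gid[ends[e, 2]])
      if (a != b) parent[max(a, b)] <- min(a, b)
    }
    comp <- vapply(seq_along(genes), find, integer(1))
    touch <- lapply(terms, function(tm) {
      gc <- ids[!is_gg[ids]]
      gc <- gc[ends[gc, 1] == tm | ends[gc, 2] == tm]
      gs <- ifelse(ends[gc, 1] == tm, ends[gc, 2], ends[gc, 1])
      unique(comp[gid[gs]])
    })
    M <- matrix(FALSE, length(terms), length(terms))
    for (i in seq_along(terms)) for (j in seq_along(terms))
      if (i < j) M[i, j] <- length(intersect(touch[[i]], touch[[j]])) > 0
    M
  }
  need <- pair_feasible(seq_len(E))
  best <- Inf; best_edges <- integer(0)
  for (mask in 0:(2^E - 1)) {
    ids <- which(bitwAnd(mask, 2^(seq_len(E) - 1)) > 0)
    cost <- sum(w[ids])
    if (cost >= best) next
    M <- pair_feasible(ids)
    if (all(M[need])) { best <- cost; best_edges <- ids }
  }
  list(cost = best, edges = best_edges)
}
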