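# Gene regulatory networks from paired scRNA/scATAC data: TF binding
# affinities over ATAC peaks, regulatory-intensity (RI) scores, per-cluster
# regulons, regulon activity scores (RAS), cell-type-specific regulon
# (CTSR) testing and master-TF ranking.

#' TF-peak binding affinities from a motif binding-site track
#'
#' Sites carry JASPAR-convention p-value scores (\code{-log10(p) * 100}, 0
#' to 1000). Sites scoring below 500 are dropped (strict "less than"); a
#' surviving site contributes \code{score / 100} to every peak it overlaps
#' (any base-pair overlap of half-open intervals). Scores outside [0, 1000]
#' are clamped with a warning. Retained affinities hence lie in [5, 10].
#'
#' @param sites data.frame chrom/start/end/name/score where \code{name} is
#'   the TF identifier (0-based half-open coordinates).
#' @param peaks data.frame chrom/start/end/name of ATAC peaks.
#' @param min_score retention threshold (default 500).
#' @return data.frame (tf, peak, affinity); at most one row per (tf, peak),
#'   keeping the strongest site.
#' @export
binding_affinity <- function(sites, peaks, min_score = 500) {
  sc <- sites$score
  if (any(sc < 0 | sc > 1000, na.rm = TRUE)) {
    warning("binding_affinity: scores outside [0, 1000] clamped")
    sc <- pmin(pmax(sc, 0), 1000)
  }
  keep <- !is.na(sc) & sc >= min_score
  sites <- sites[keep, , drop = FALSE]; sc <- sc[keep]
  if (nrow(sites) == 0)
    return(data.frame(tf = character(), peak = character(),
                      affinity = numeric()))
  sg <- GenomicRanges::GRanges(sites$chrom,
                               IRanges::IRanges(sites$start + 1, sites$end))
  pg <- GenomicRanges::GRanges(peaks$chrom,
                               IRanges::IRanges(peaks$start + 1, peaks$end))
  ov <- GenomicRanges::findOverlaps(sg, pg)
  if (length(ov) == 0)
    return(data.frame(tf = character(), peak = character(),
                      affinity = numeric()))
  df <- data.frame(tf = sites$name[S4Vectors::queryHits(ov)],
                   peak = peaks$name[S4Vectors::subjectHits(ov)],
                   affinity = sc[S4Vectors::queryHits(ov)] / 100,
                   stringsAsFactors = FALSE)
  # several sites of one TF may hit one peak: keep the strongest
  agg <- stats::aggregate(affinity ~ tf + peak, df, max)
  agg[order(agg$tf, agg$peak), , drop = FALSE]
}

#' Regulatory-intensity scores of one TF
#'
#' \code{s_ij|q = sum_k b_qk * w_ik * x^A_kj}, summing over peaks both bound
#' by TF q and assigned to gene i; linear in the accessibility counts.
#'
#' @param affinity data.frame from [binding_affinity()] (rows of one or
#'   several TFs).
#' @param w peak-gene weight data.frame from [peak_gene_weights()].
#' @param atac \code{named_matrix} of peak counts.
#' @param tf TF identifier (one of \code{affinity$tf}).
#' @param genes gene universe (default: genes in \code{w}).
#' @return genes x cells matrix of RI scores s_ij|q.
#' @export
ri_score <- function(affinity, w, atac, tf, genes = unique(w$gene)) {
  aff <- affinity[affinity$tf == tf, , drop = FALSE]
  v <- atac$values
  out <- matrix(0, length(genes), ncol(v),
                dimnames = list(genes, colnames(v)))
  if (nrow(aff) == 0) return(out)
  m <- merge(w, aff, by = "peak")      # peaks assigned to gene AND bound
  m <- m[m$peak %in% rownames(v) & m$gene %in% genes, , drop = FALSE]
  if (nrow(m) == 0) return(out)
  gi <- match(m$gene, genes)
  ki <- match(m$peak, rownames(v))
  W <- Matrix::sparseMatrix(i = gi, j = ki, x = m$weight * m$affinity,
                            dims = c(length(genes), nrow(v)))
  out[] <- as.matrix(W %*% v)
  out
}

#' Assemble per-cluster regulons
#'
#' For each cluster's active gene association network, TF q's regulon is the
#' set of network genes with positive RI in at least one cluster cell;
#' regulons with fewer than \code{min_targets} targets are dropped (a
#' single-gene "regulon" is not a module and breaks centrality).
#'
#' @param networks list of \code{gene_network} objects (one per cluster).
#' @param affinity data.frame from [binding_affinity()].
#' @param w peak-gene weights.
#' @param atac \code{named_matrix} of peak counts.
#' @param labels a \code{cluster_labeling}.
#' @param min_targets minimum regulon size (default 2).
#' @return list of \code{regulon} objects: \code{tf}, \code{cluster},
#'   \code{targets}, \code{ri} (targets x cluster-cells RI matrix).
#' @export
assemble_regulons <- function(networks, affinity, w, atac, labels,
                              min_targets = 2) {
  tfs <- unique(affinity$tf)
  out <- list()
  for (net in networks) {
    z <- net$cluster
    cells <- intersect(cluster_cells(labels, z), colnames(atac$values))
    genes <- net$genes$gene
    if (!length(genes) || !length(cells)) next
    for (tf in tfs) {
      s <- ri_score(affinity, w, atac, tf, genes = genes)
      s <- s[, cells, drop = FALSE]
      targets <- rownames(s)[rowSums(s) > 0]
      if (length(targets) < min_targets) next
      out[[length(out) + 1]] <- structure(
        list(tf = tf, cluster = z, targets = targets,
             ri = s[targets, , drop = FALSE]),
        class = "regulon")
    }
  }
  if (!length(out)) warning("assemble_regulons: no regulon assembled")
  out
}

#' @export
print.regulon <- function(x, ...) {
  cat(sprintf("<regulon> TF %s in cluster %d: %d targets\n",
              x$tf, x$cluster, length(x$targets)))
  invisible(x)
}

#' Regulon activity score
#'
#' \code{r(q,z) = sum_{i in I_q} sum_{j in C[z]} x_ij * s_ij|q / denom} with
#' \code{denom = |I_q| * |C[z]|} under the default \code{"subset"}
#' denominator (invariant to replicating cluster cells) or the literal
#' \code{I * J} (all genes x all cells) under \code{"global"}.
#'
#' @param regulon a \code{regulon}.
#' @param X the integrated (GAS) matrix.
#' @param labels,z cluster labeling and cluster id.
#' @param denominator \code{"subset"} (default) or \code{"global"}.
#' @return scalar RAS.
#' @export
ras <- function(regulon, X, labels, z = regulon$cluster,
                denominator = c("subset", "global")) {
  denominator <- match.arg(denominator)
  if (!length(regulon$targets)) stop("ras: empty regulon")
  cells <- intersect(cluster_cells(labels, z), colnames(X$values))
  xs <- X$values[regulon$targets, cells, drop = FALSE]
  s <- regulon$ri[, intersect(cells, colnames(regulon$ri)), drop = FALSE]
  num <- sum(xs[, colnames(s), drop = FALSE] * s)
  den <- if (denominator == "subset") length(regulon$targets) * length(cells)
         else nrow(X$values) * ncol(X$values)
  num / den
}

#' Per-cell regulon activity
#'
#' \code{r_j(q) = sum_{i in I_q} x_ij * s_ij|q / |I_q|}; the cell-level
#' quantity the CTSR rank-sum test compares between clusters.
#'
#' @param tf TF identifier.
#' @param targets regulon target genes.
#' @param affinity,w,atac as in [ri_score()].
#' @param X integrated (GAS) matrix.
#' @return named numeric vector over all cells of X.
#' @export
per_cell_activity <- function(tf, targets, affinity, w, atac, X) {
  s <- ri_score(affinity, w, atac, tf, genes = targets)
  s <- s[, colnames(X$values), drop = FALSE]
  colSums(X$values[targets, , drop = FALSE] * s) / length(targets)
}

#' Cell-type-specific regulon test
#'
#' For every (TF, cluster) regulon, a one-vs-rest Wilcoxon rank-sum test of
#' the per-cell regulon activity, BH-adjusted across all tests; a regulon is
#' a CTSR iff adjusted p < 0.05 and log2 fold change of mean activity >
#' 0.10 (strict). Clusters with fewer than 3 cells are skipped (NA).
#'
#' @param regulons list of \code{regulon} objects.
#' @param affinity,w,atac as in [ri_score()].
#' @param X integrated (GAS) matrix.
#' @param labels a \code{cluster_labeling}.
#' @param p_threshold,lfc_threshold CTSR thresholds (defaults 0.05, 0.10).
#' @return data.frame (tf, cluster, ras, p, adj_p, logFC, ctsr).
#' @export
ctsr_test <- function(regulons, affinity, w, atac, X, labels,
                      p_threshold = 0.05, lfc_threshold = 0.10) {
  if (!length(regulons))
    return(data.frame(tf = character(), cluster = integer(),
                      ras = numeric(), p = numeric(), adj_p = numeric(),
                      logFC = numeric(), ctsr = logical()))
  rows <- lapply(regulons, function(rg) {
    act <- per_cell_activity(rg$tf, rg$targets, affinity, w, atac, X)
    cells_in <- intersect(cluster_cells(labels, rg$cluster), names(act))
    in_act <- act[cells_in]
    out_act <- act[setdiff(names(act), cells_in)]
    if (length(in_act) < 3 || length(out_act) < 3) {
      p <- NA_real_; lfc <- NA_real_
    } else {
      p <- stats::wilcox.test(in_act, out_act, exact = FALSE)$p.value
      lfc <- log2((mean(in_act) + 1e-9) / (mean(out_act) + 1e-9))
    }
    data.frame(tf = rg$tf, cluster = rg$cluster,
               ras = ras(rg, X, labels), p = p, logFC = lfc,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$adj_p <- stats::p.adjust(res$p, method = "BH")
  res$ctsr <- !is.na(res$adj_p) & res$adj_p < p_threshold &
    res$logFC > lfc_threshold
  res[, c("tf", "cluster", "ras", "p", "adj_p", "logFC", "ctsr")]
}

#' Rank master TFs of a cluster GRN by eigenvector centrality
#'
#' The cluster GRN is the union of its regulons (TF -> target edges
#' weighted by mean RI over cluster cells); centrality is computed on the
#' symmetrized weighted adjacency, the principal eigenvector being
#' non-negative and unit-normalized. Ties break lexicographically.
#'
#' @param regulons list of \code{regulon} objects of one cluster.
#' @param top_n number of TFs returned (default 10).
#' @return data.frame (tf, centrality) sorted by decreasing centrality.
#' @export
master_tfs <- function(regulons, top_n = 10) {
  if (!length(regulons))
    return(data.frame(tf = character(), centrality = numeric()))
  el <- do.call(rbind, lapply(regulons, function(rg) {
    data.frame(from = rg$tf, to = rg$targets,
               weight = rowMeans(rg$ri), stringsAsFactors = FALSE)
  }))
  el <- stats::aggregate(weight ~ from + to, el, mean)
  nodes <- sort(unique(c(el$from, el$to)))
  A <- matrix(0, length(nodes), length(nodes),
              dimnames = list(nodes, nodes))
  A[cbind(el$from, el$to)] <- el$weight
  A <- pmax(A, t(A))                       # symmetrize
  ec <- eigenvector_centrality_matrix(A)
  tfs <- sort(unique(el$from))
  res <- data.frame(tf = tfs, centrality = ec[tfs])
  res <- res[order(-res$centrality, res$tf), , drop = FALSE]
  rownames(res) <- NULL
  utils::head(res, top_n)
}

#' Export a regulon table (cluster, TF, gene, mean RI) as TSV
#'
#' @param regulons list of \code{regulon} objects.
#' @param path output path.
#' @export
write_regulons <- function(regulons, path) {
  df <- do.call(rbind, lapply(regulons, function(rg) {
    data.frame(cluster = rg$cluster, tf = rg$tf, gene = rg$targets,
               mean_ri = rowMeans(rg$ri), stringsAsFactors = FALSE)
  }))
  if (is.null(df)) df <- data.frame(cluster = integer(), tf = character(),
                                    gene = character(), mean_ri = numeric())
  df <- df[order(df$cluster, df$tf, df$gene), , drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
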