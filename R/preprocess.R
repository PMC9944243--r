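#' Quality-control filter on a count matrix
#'
#' A row or column is removed when it carries fewer non-zero entries than
#' \code{min_nonzero_fraction} of the surviving opposite dimension (strict
#' "less than", so a row exactly at the threshold is retained). Filtering
#' iterates to a fixed point and is idempotent. Optional total-count and
#' mitochondrial-fraction thresholds are off by default.
#'
#' @param m a \code{named_matrix}.
#' @param min_nonzero_fraction minimum fraction of non-zero entries
#'   (default 0.001).
#' @param min_counts minimum total counts per cell (default 0 = off).
#' @param max_mito_fraction maximum fraction of counts on mitochondrial
#'   features (rows matching \code{mito_pattern}); default 1 = off.
#' @param mito_pattern regex identifying mitochondrial feature names.
#' @return filtered \code{named_matrix}.
#' @export
qc_filter <- function(m, min_nonzero_fraction = 0.001, min_counts = 0,
                      max_mito_fraction = 1, mito_pattern = "^(MT-|mt-)") {
  stopifnot(inherits(m, "named_matrix"))
  if (min_nonzero_fraction < 0 || min_nonzero_fraction > 1)
    stop("qc_filter: min_nonzero_fraction must be in [0,1]")
  v <- m$values
  if (min_counts > 0) v <- v[, colSums(v) >= min_counts, drop = FALSE]
  if (max_mito_fraction < 1) {
    mito <- grepl(mito_pattern, rownames(v))
    if (any(mito)) {
      frac <- colSums(v[mito, , drop = FALSE]) / pmax(colSums(v), 1e-300)
      v <- v[, frac <= max_mito_fraction, drop = FALSE]
    }
  }
  repeat {
    keep_r <- rowSums(v != 0) >= min_nonzero_fraction * ncol(v)
    v2 <- v[keep_r, , drop = FALSE]
    keep_c <- colSums(v2 != 0) >= min_nonzero_fraction * nrow(v2)
    v2 <- v2[, keep_c, drop = FALSE]
    if (nrow(v2) == 0 || ncol(v2) == 0)
      stop("qc_filter: all rows or columns removed")
    if (identical(dim(v2), dim(v))) break
    v <- v2
  }
  named_matrix(v2, modality = m$modality)
}

#' Depth-normalize and log-transform counts
#'
#' Each cell is scaled to a fixed total (\code{scale}) and log1p-transformed,
#' so \code{colSums(expm1(values))} equals \code{scale} for every non-empty
#' cell.
#'
#' @param m a \code{named_matrix} of non-negative counts.
#' @param scale per-cell target total (default 1e4).
#' @return log-normalized \code{named_matrix}.
#' @export
log_normalize <- function(m, scale = 1e4) {
  v <- m$values
  cs <- colSums(v)
  if (any(cs == 0)) stop("log_normalize: all-zero column (run qc_filter first)")
  nm_replace(m, log1p(sweep(v, 2, cs, "/") * scale))
}

#' Select highly variable genes
#'
#' Ranks genes by variance-stabilized dispersion: a loess trend of
#' log10(variance) on log10(mean) is fitted, observations are standardized by
#' the trend (clipped at sqrt(n)), and genes are ranked by the variance of the
#' standardized values. With fewer than \code{n} genes, all are kept.
#'
#' @param m a log-normalized \code{named_matrix}.
#' @param n number of genes to keep (default 2000).
#' @return \code{named_matrix} restricted to the selected genes, in original
#'   row order.
#' @export
select_hvg <- function(m, n = 2000) {
  if (n <= 0) stop("select_hvg: n must be positive")
  v <- m$values
  if (nrow(v) <= n) return(m)
  mu <- rowMeans(v)
  va <- apply(v, 1, stats::var)
  disp <- rep(0, nrow(v))
  ok <- va > 0 & mu > 0
  if (sum(ok) > 10) {
    fit <- stats::loess(log10(va[ok]) ~ log10(mu[ok]), span = 0.3,
                        degree = 2, family = "symmetric")
    sd_exp <- sqrt(10^stats::fitted(fit))
    clip <- sqrt(ncol(v))
    z <- sweep(v[ok, , drop = FALSE], 1, mu[ok], "-")
    z <- sweep(z, 1, sd_exp, "/")
    z <- pmin(pmax(z, -clip), clip)
    disp[ok] <- apply(z, 1, stats::var)
  } else {
    disp[ok] <- va[ok]
  }
  keep <- sort(order(disp, decreasing = TRUE)[seq_len(n)])
  nm_subset(m, rows = keep)
}

#' Align multiple expression matrices into one integrated matrix
#'
#' A basic canonical-correlation alignment: matrices are restricted to their
#' shared gene set, canonical cell loadings are obtained from the SVD of the
#' standardized cross-covariance with the first (reference) batch, and batch
#' effects are removed anchor-free by matching per-gene means to the
#' reference. Corrected values are clipped at zero. A single input passes
#' through unchanged.
#'
#' @param matrices list of log-normalized \code{named_matrix} objects sharing
#'   a gene namespace (intersection is taken).
#' @param n_components number of canonical components retained in the
#'   \code{"cca"} attribute (default 20).
#' @return an \code{integrated_matrix}: genes x (union of cells), with
#'   attributes \code{source = "multi_rna"} and \code{cca} (cell loadings).
#' @export
cca_align <- function(matrices, n_components = 20) {
  stopifnot(length(matrices) >= 1)
  if (length(matrices) == 1) {
    return(integrated_matrix(matrices[[1]]$values, source = "multi_rna"))
  }
  shared <- Reduce(intersect, lapply(matrices, function(m) rownames(m$values)))
  if (length(shared) < 30)
    stop("cca_align: fewer than 30 shared genes")
  mats <- lapply(matrices, function(m) m$values[shared, , drop = FALSE])
  all_cells <- unlist(lapply(mats, colnames))
  if (anyDuplicated(all_cells))
    stop("cca_align: duplicate cell barcodes across batches")
  ref_mu <- rowMeans(mats[[1]])
  cca_load <- vector("list", length(mats))
  std <- function(v) {
    v <- v - rowMeans(v)
    s <- sqrt(rowSums(v^2)); s[s == 0] <- 1
    v / s
  }
  a <- std(mats[[1]])
  corrected <- mats
  for (b in seq_along(mats)) {
    if (b > 1) {
      k <- min(n_components, ncol(mats[[1]]) - 1, ncol(mats[[b]]) - 1)
      sv <- svd(crossprod(a, std(mats[[b]])), nu = k, nv = k)
      cca_load[[1]] <- sv$u
      cca_load[[b]] <- sv$v
      shift <- rowMeans(mats[[b]]) - ref_mu
      corrected[[b]] <- mats[[b]] - shift
    }
  }
  out <- pmax(do.call(cbind, corrected), 0)
  res <- integrated_matrix(out, source = "multi_rna")
  attr(res, "cca") <- cca_load
  res
}

#' Centered log-ratio transform for CITE-seq gene + protein matrices
#'
#' \code{CLR(x_ij) = log(1 + x_ij / exp(mean_{i in Z_j} log(1 + x_ij)))} with
#' \code{Z_j} the non-zero features of cell j: the denominator is the
#' geometric mean of (1 + x) over detected features, so zeros map to zero and
#' each cell is transformed independently.
#'
#' @param m a \code{named_matrix} (vertically concatenated genes + proteins).
#' @return transformed \code{named_matrix}.
#' @export
clr_transform <- function(m) {
  v <- m$values
  nz <- colSums(v != 0)
  if (any(nz == 0)) stop("clr_transform: cell with no non-zero features")
  geo <- exp(colSums(log1p(v)) / nz)   # zeros contribute log1p(0)=0 to the sum
  nm_replace(m, log1p(sweep(v, 2, geo, "/")))
}

#' Regulatory-potential weights of ATAC peaks for genes
#'
#' Distance-decay weighting of peak accessibility toward gene activity:
#' \itemize{
#'   \item 0 when the peak centre is more than \code{dmax} from the gene TSS,
#'     or when the peak centre falls inside the transcript span of a
#'     different gene;
#'   \item \code{1/exon_length(gene)} when the peak overlaps an exon of the
#'     gene;
#'   \item \code{2^(-d/d0)} otherwise, with \code{d} the unsigned distance
#'     between peak centre and TSS.
#' }
#'
#' @param peaks data.frame chrom/start/end/name (0-based half-open).
#' @param genes gene annotation list from [read_gene_annotation()].
#' @param d0 half-decay distance in bp (default 10000).
#' @param dmax hard truncation distance in bp (default 150000).
#' @return data.frame (gene, peak, weight), one row per non-zero weight.
#' @export
peak_gene_weights <- function(peaks, genes, d0 = 10000, dmax = 150000) {
  if (any(vapply(genes, function(g) g$exon_length, numeric(1)) <= 0))
    stop("peak_gene_weights: gene with zero exon length")
  centers <- (peaks$start + peaks$end) / 2
  gene_ids <- vapply(genes, function(g) g$gene_id, character(1))
  spans <- data.frame(
    chrom = vapply(genes, function(g) g$chrom, character(1)),
    lo = vapply(genes, function(g) g$span[1], numeric(1)),
    hi = vapply(genes, function(g) g$span[2], numeric(1)))
  out <- vector("list", length(genes))
  for (gi in seq_along(genes)) {
    g <- genes[[gi]]
    same_chr <- which(peaks$chrom == g$chrom)
    if (!length(same_chr)) next
    d <- abs(centers[same_chr] - g$tss)
    cand <- same_chr[d <= dmax]
    if (!length(cand)) next
    d <- d[d <= dmax]
    # peak centre inside another gene's transcript span -> excluded
    in_other <- vapply(cand, function(p) {
      c0 <- centers[p]
      any(spans$chrom == peaks$chrom[p] & spans$lo <= c0 & c0 < spans$hi &
            gene_ids != g$gene_id)
    }, logical(1))
    w <- 2^(-d / d0)
    # exon overlap (any base-pair, half-open intervals)
    ov <- vapply(cand, function(p) {
      any(peaks$start[p] < g$exons$end & g$exons$start < peaks$end[p])
    }, logical(1))
    w[ov] <- 1 / g$exon_length
    keep <- !in_other | ov   # exonic overlap of the gene itself wins
    keep <- keep & w > 0
    if (any(keep))
      out[[gi]] <- data.frame(gene = g$gene_id,
                              peak = peaks$name[cand[keep]],
                              weight = w[keep], stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(gene = character(), peak = character(),
                      weight = numeric())
  rownames(res) <- NULL
  res
}

#' Gene regulatory-potential matrix from peak accessibility
#'
#' \code{x'_ij = sum_k w_ik * x^A_kj}: peak counts are collapsed to genes by
#' the regulatory-potential weights. Genes with an all-zero result are
#' flagged (attribute \code{"zero_genes"}) for joint removal with the
#' velocity matrix.
#'
#' @param atac \code{named_matrix} of peak counts (rows = peak names matching
#'   \code{w$peak}).
#' @param w weight data.frame from [peak_gene_weights()].
#' @param genes optional character vector fixing the gene universe/order.
#' @return \code{named_matrix} (modality \code{"gas"}) genes x cells.
#' @export
regulatory_potential <- function(atac, w, genes = unique(w$gene)) {
  if (nrow(w) == 0) stop("regulatory_potential: no peak maps to any gene")
  v <- atac$values
  w <- w[w$peak %in% rownames(v), , drop = FALSE]
  if (nrow(w) == 0) stop("regulatory_potential: no weighted peak present in matrix")
  gi <- match(w$gene, genes)
  ki <- match(w$peak, rownames(v))
  W <- Matrix::sparseMatrix(i = gi[!is.na(gi)], j = ki[!is.na(gi)],
                            x = w$weight[!is.na(gi)],
                            dims = c(length(genes), nrow(v)))
  out <- as.matrix(W %*% v)
  rownames(out) <- genes
  colnames(out) <- colnames(v)
  res <- named_matrix(out, modality = "gas")
  attr(res, "zero_genes") <- genes[rowSums(out != 0) == 0]
  res
}

#' Discretize gene expression into regulatory-signal labels
#'
#' A simplified left-truncated mixture model: per gene, a Gaussian mixture
#' (unequal variances, components selected by BIC up to
#' \code{max_components}) is fitted on the non-zero log-expression values,
#' i.e. above the detection limit. Cells are labeled by their most probable
#' component, components are ordered by increasing mean, and zero-expression
#' cells receive the lowest label. Genes detected in fewer than 5 cells get a
#' single component without fitting.
#'
#' @param rna log-normalized \code{named_matrix}.
#' @param max_components maximum number of mixture components (default 5).
#' @return object of class \code{ltmg_labels}: integer \code{labels} matrix
#'   (genes x cells, values in 1..G_i) and integer vector
#'   \code{n_components}.
#' @importFrom mclust Mclust mclustBIC
#' @export
ltmg_discretize <- function(rna, max_components = 5) {
  v <- rna$values
  labels <- matrix(1L, nrow(v), ncol(v), dimnames = dimnames(v))
  G <- stats::setNames(rep(1L, nrow(v)), rownames(v))
  for (i in seq_len(nrow(v))) {
    x <- v[i, ]
    nz <- which(x > 0)
    if (length(nz) < 5 || stats::sd(x[nz]) == 0) next
    fit <- tryCatch(
      suppressWarnings(Mclust(x[nz], G = 1:max_components,
                              modelNames = "V", verbose = FALSE)),
      error = function(e) NULL)
    if (is.null(fit)) next
    ord <- order(fit$parameters$mean)
    relab <- match(seq_along(ord), ord)
    labels[i, nz] <- as.integer(relab[fit$classification])
    G[i] <- as.integer(fit$G)
  }
  structure(list(labels = labels, n_components = G), class = "ltmg_labels")
}

#' Velocity weights for expression/accessibility balancing
#'
#' Velocities are first smoothed within each (gene, discretization-label)
#' cell group by the group mean. For a positive velocity, ranks \code{a}
#' (within the gene's positive velocities) and \code{b} (within the cell's
#' positive velocities) are taken descending starting at 1 and
#' \code{beta+ = sqrt((n_i - a - 1)^2 + (n_j - b - 1)^2)} with \code{n_i},
#' \code{n_j} the positive-set sizes. For a negative velocity the analogous
#' form uses ranks by absolute velocity descending starting at 0 over the
#' negative sets. With \code{normalize = TRUE} (default) beta is divided by
#' \code{sqrt(n_i^2 + n_j^2)}, bounding it by sqrt(2) so the downstream
#' activity score stays non-negative; \code{normalize = FALSE} reproduces the
#' raw unbounded weights. Entries with zero velocity (or an empty
#' positive/negative set) get beta = 0.
#'
#' @param vel \code{named_matrix} of velocities (modality \code{"velocity"}).
#' @param ltmg optional \code{ltmg_labels} for group-mean smoothing.
#' @param normalize logical (default TRUE), see above.
#' @return object of class \code{velocity_weights}: matrices \code{beta}
#'   (>= 0) and \code{sign} in \{-1, 0, 1\}.
#' @export
velocity_weights <- function(vel, ltmg = NULL, normalize = TRUE) {
  v <- vel$values
  if (!is.null(ltmg)) {
    stopifnot(identical(dim(ltmg$labels), dim(v)))
    for (i in seq_len(nrow(v))) {
      lab <- ltmg$labels[i, ]
      v[i, ] <- stats::ave(v[i, ], lab)
    }
  }
  beta <- matrix(0, nrow(v), ncol(v), dimnames = dimnames(v))
  sgn <- sign(v)
  pos_gene_n <- rowSums(v > 0); neg_gene_n <- rowSums(v < 0)
  pos_cell_n <- colSums(v > 0); neg_cell_n <- colSums(v < 0)
  # descending ranks within positive entries of each gene / cell
  rank_desc <- function(x, start1) {
    r <- rank(-x, ties.method = "average")
    if (start1) r else r - 1
  }
  a_pos <- b_pos <- a_neg <- b_neg <- matrix(NA_real_, nrow(v), ncol(v))
  for (i in seq_len(nrow(v))) {
    p <- v[i, ] > 0
    if (any(p)) a_pos[i, p] <- rank_desc(v[i, p], start1 = TRUE)
    n <- v[i, ] < 0
    if (any(n)) a_neg[i, n] <- rank_desc(abs(v[i, n]), start1 = FALSE)
  }
  for (j in seq_len(ncol(v))) {
    p <- v[, j] > 0
    if (any(p)) b_pos[p, j] <- rank_desc(v[p, j], start1 = TRUE)
    n <- v[, j] < 0
    if (any(n)) b_neg[n, j] <- rank_desc(abs(v[n, j]), start1 = FALSE)
  }
  pos <- which(v > 0)
  if (length(pos)) {
    ni <- pos_gene_n[row(v)[pos]]; nj <- pos_cell_n[col(v)[pos]]
    b <- sqrt((ni - a_pos[pos] - 1)^2 + (nj - b_pos[pos] - 1)^2)
    if (normalize) b <- b / sqrt(ni^2 + nj^2)
    beta[pos] <- b
  }
  neg <- which(v < 0)
  if (length(neg)) {
    ni <- neg_gene_n[row(v)[neg]]; nj <- neg_cell_n[col(v)[neg]]
    b <- sqrt((ni - a_neg[neg] - 1)^2 + (nj - b_neg[neg] - 1)^2)
    if (normalize) b <- b / sqrt(ni^2 + nj^2)
    beta[neg] <- b
  }
  structure(list(beta = beta, sign = sgn, smoothed_velocity = v),
            class = "velocity_weights")
}

#' Steady-state RNA velocity estimator from spliced/unspliced counts
#'
#' Per gene, the degradation/splicing ratio gamma is fitted on the cells in
#' the upper \code{quantile} of spliced+unspliced abundance by regression
#' through the origin of unspliced on spliced; velocity is
#' \code{v = u - gamma * s}.
#'
#' @param spliced,unspliced \code{named_matrix} objects of identical shape.
#' @param quantile upper-quantile fraction used for the fit (default 0.95).
#' @return \code{named_matrix} of velocities (modality \code{"velocity"}).
#' @export
steady_state_velocity <- function(spliced, unspliced, quantile = 0.95) {
  s <- spliced$values; u <- unspliced$values
  stopifnot(identical(dim(s), dim(u)))
  v <- matrix(0, nrow(s), ncol(s), dimnames = dimnames(s))
  for (i in seq_len(nrow(s))) {
    tot <- s[i, ] + u[i, ]
    top <- tot >= stats::quantile(tot, quantile)
    ss <- s[i, top]; uu <- u[i, top]
    gamma <- if (sum(ss^2) > 0) sum(uu * ss) / sum(ss^2) else 0
    v[i, ] <- u[i, ] - gamma * s[i, ]
  }
  named_matrix(v, modality = "velocity")
}

#' Gene activity score (GAS) matrix
#'
#' Velocity-weighted combination of expression and regulatory potential:
#' \code{x^G = x^R + (1 + beta+) x^A'} where velocity is positive,
#' \code{x^R + (1 - beta-) x^A'} where negative, and \code{x^R + x^A'} where
#' zero. With \code{clip_negative = TRUE} (default) the result is clipped at
#' zero, keeping the edge definition (x > 0) of the downstream graph valid.
#'
#' @param rna log-normalized expression \code{named_matrix}.
#' @param regpot regulatory-potential \code{named_matrix} from
#'   [regulatory_potential()].
#' @param vw \code{velocity_weights}; NULL treats all velocities as zero.
#' @param clip_negative logical, clip result at 0 (default TRUE).
#' @return an \code{integrated_matrix} with \code{source = "rna_atac"}.
#' @export
gas_matrix <- function(rna, regpot, vw = NULL, clip_negative = TRUE) {
  xr <- rna$values; xa <- regpot$values
  if (!identical(dim(xr), dim(xa)) ||
      !identical(rownames(xr), rownames(xa)) ||
      !identical(colnames(xr), colnames(xa)))
    stop("gas_matrix: shape or name mismatch between rna and regpot")
  if (is.null(vw)) {
    g <- xr + xa
  } else {
    stopifnot(identical(dim(vw$beta), dim(xr)))
    mult <- matrix(1, nrow(xr), ncol(xr))
    mult[vw$sign > 0] <- 1 + vw$beta[vw$sign > 0]
    mult[vw$sign < 0] <- 1 - vw$beta[vw$sign < 0]
    g <- xr + mult * xa
  }
  if (clip_negative) g <- pmax(g, 0)
  integrated_matrix(g, source = "rna_atac")
}

#' Construct an integrated matrix
#'
#' @param values non-negative features x cells matrix with dimnames.
#' @param source one of \code{"multi_rna"}, \code{"cite"}, \code{"rna_atac"}.
#' @param feature_kind per-row \code{"gene"}/\code{"protein"} (default all
#'   gene).
#' @return an \code{integrated_matrix}.
#' @export
integrated_matrix <- function(values, source = c("multi_rna", "cite",
                                                 "rna_atac"),
                              feature_kind = NULL) {
  source <- match.arg(source)
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("integrated_matrix: dimnames required")
  if (is.null(feature_kind)) feature_kind <- rep("gene", nrow(values))
  structure(list(values = values, feature_kind = feature_kind,
                 source = source),
            class = c("integrated_matrix"))
}

#' @export
print.integrated_matrix <- function(x, ...) {
  cat(sprintf("<integrated_matrix> %d features x %d cells (source %s)\n",
              nrow(x$values), ncol(x$values), x$source))
  invisible(x)
}

#' @export
dim.integrated_matrix <- function(x) dim(x$values)
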