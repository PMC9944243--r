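# Synthetic multi-omic fixtures with planted ground truth: negative-binomial
# counts with cluster-specific differential genes and Bernoulli dropout,
# CITE-seq protein counts correlated with coding genes, and a paired
# RNA+ATAC layout with distance-structured peaks, planted regulons and
# planted velocity signs. Everything is seed-deterministic.

#' Fixture specification
#'
#' @param n_cells,n_genes,n_clusters,n_proteins,n_peaks,n_tfs sizes.
#' @param de_fraction fraction of genes differentially expressed per cluster
#'   (disjoint across clusters; default 0.1).
#' @param de_fold fold change of DE genes in their cluster (default 8).
#' @param dropout Bernoulli dropout probability (default 0.3).
#' @param rho target protein / coding-gene correlation (CITE fixtures).
#' @param seed RNG seed.
#' @return a \code{fixture_spec} list.
#' @export
fixture_spec <- function(n_cells = 300, n_genes = 500, n_clusters = 3,
                         n_proteins = 30, n_peaks = 2 * n_genes + 10,
                         n_tfs = 3, de_fraction = 0.1, de_fold = 8,
                         dropout = 0.3, rho = 0.7, seed = 1) {
  stopifnot(n_cells > 0, n_genes > 0, n_clusters >= 1,
            de_fraction >= 0, de_fraction <= 1, dropout >= 0, dropout < 1)
  structure(as.list(environment()), class = "fixture_spec")
}

#' Simulate an scRNA-seq count matrix with planted cell clusters
#'
#' Negative-binomial counts with log-normal baseline means and gamma
#' dispersions; per cluster, a disjoint \code{de_fraction} of genes is
#' up-shifted by \code{de_fold}; Bernoulli dropout thins the counts.
#'
#' @param spec a [fixture_spec()].
#' @param batch integer tag appended to barcodes (for multi-batch fixtures).
#' @return list: \code{counts} (\code{named_matrix}), \code{truth} (list
#'   with \code{cell_labels}, \code{de_genes} per cluster).
#' @export
make_rna <- function(spec, batch = 1) {
  if (spec$n_clusters >= 2 && spec$de_fraction * spec$n_genes < 1)
    stop("make_rna: de_fraction too small to plant any DE gene")
  set.seed(spec$seed + 1000 * batch)
  I <- spec$n_genes; J <- spec$n_cells; Z <- spec$n_clusters
  labels <- sort(rep_len(seq_len(Z), J))
  mu <- stats::rlnorm(I, meanlog = 0.5, sdlog = 1)
  size <- stats::rgamma(I, shape = 2, rate = 0.5)   # NB size ~ Gamma
  n_de <- floor(spec$de_fraction * I)
  de_genes <- split(seq_len(min(Z * n_de, I)),
                    rep(seq_len(Z), each = n_de)[seq_len(min(Z * n_de, I))])
  M <- matrix(mu, I, J)
  for (z in seq_len(Z))
    M[de_genes[[z]], labels == z] <- M[de_genes[[z]], labels == z] *
      spec$de_fold
  counts <- matrix(stats::rnbinom(I * J, mu = M, size = size), I, J)
  if (spec$dropout > 0)
    counts <- counts * matrix(stats::rbinom(I * J, 1, 1 - spec$dropout),
                              I, J)
  gene_ids <- sprintf("gene%03d", seq_len(I))
  barcodes <- sprintf("cell%03d_b%d", seq_len(J), batch)
  rownames(counts) <- gene_ids; colnames(counts) <- barcodes
  truth <- list(cell_labels = stats::setNames(labels, barcodes),
                de_genes = lapply(de_genes, function(ix) gene_ids[ix]))
  list(counts = named_matrix(counts, modality = "rna"), truth = truth)
}

#' Simulate a CITE-seq fixture (paired gene + surface-protein counts)
#'
#' Protein counts follow a Gaussian-copula link to their designated coding
#' gene: on the log1p scale the latent protein signal is
#' \code{rho * z_gene + sqrt(1-rho^2) * noise}.
#'
#' @param spec a [fixture_spec()].
#' @return list: \code{rna}, \code{protein} (\code{named_matrix}),
#'   \code{truth} (adds \code{coding_gene} map).
#' @export
make_cite <- function(spec) {
  stopifnot(spec$n_proteins <= spec$n_genes)
  base <- make_rna(spec)
  set.seed(spec$seed + 77)
  counts <- base$counts$values
  # proteins track DE genes first so they carry cluster signal
  de_all <- unlist(base$truth$de_genes, use.names = FALSE)
  coding <- c(de_all, setdiff(rownames(counts), de_all))[
    seq_len(spec$n_proteins)]
  zg <- t(scale(t(log1p(counts[coding, , drop = FALSE]))))
  zg[is.na(zg)] <- 0
  rho <- spec$rho
  zp <- rho * zg + sqrt(1 - rho^2) *
    matrix(stats::rnorm(length(zg)), nrow(zg), ncol(zg))
  prot <- round(exp(log(50) + 0.8 * zp))   # ADT-like depth, log-linear link
  rownames(prot) <- paste0("adt_", coding)
  truth <- base$truth
  truth$coding_gene <- stats::setNames(coding, rownames(prot))
  list(rna = base$counts,
       protein = named_matrix(prot, modality = "protein"),
       truth = truth)
}

# deterministic genome layout: one chromosome, genes every 500 kb on the +
# strand with two exons of 500 bp (total exon length 1000)
synthetic_gene_annotation <- function(gene_ids) {
  ann <- lapply(seq_along(gene_ids), function(i) {
    tss <- 500000 * i
    exons <- data.frame(start = c(tss, tss + 1500),
                        end = c(tss + 500, tss + 2000))
    list(gene_id = gene_ids[i], chrom = "chr1", strand = "+", tss = tss,
         exons = exons, span = c(tss, tss + 2000), exon_length = 1000L)
  })
  names(ann) <- gene_ids
  ann
}

#' Simulate a paired scRNA + scATAC fixture with planted regulons
#'
#' Genes sit on one synthetic chromosome, 500 kb apart. Each gene gets a
#' promoter peak (1 kb upstream) and a distal peak (10 kb upstream, the
#' half-decay distance); a handful of extra peaks sit beyond the 150 kb
#' truncation bound or inside exons to exercise the weighting cases. Peaks
#' of cluster-z DE genes are accessible mainly in cluster z. Each of
#' \code{n_tfs} planted TFs binds the promoter peaks of one cluster's DE
#' genes (JASPAR-convention site score 900); 20 null TFs bind promoter
#' peaks of randomly chosen non-DE genes (score 700), and sub-threshold
#' sites (score 400) are added for the filtering path. Spliced/unspliced
#' matrices encode planted velocity signs: DE genes are induced (positive)
#' in their active cluster and repressed (negative) elsewhere.
#'
#' @param spec a [fixture_spec()].
#' @param n_null_tfs number of background TFs (default 20).
#' @return list: \code{rna}, \code{atac}, \code{spliced}, \code{unspliced}
#'   (\code{named_matrix}), \code{peaks} (BED-like data.frame),
#'   \code{genes} (annotation list), \code{motifs} (BED5-like data.frame),
#'   \code{truth} (cell labels, regulon map, peak-gene map, velocity signs).
#' @export
make_rna_atac <- function(spec, n_null_tfs = 20) {
  stopifnot(spec$n_peaks >= spec$n_genes)
  base <- make_rna(spec)
  set.seed(spec$seed + 333)
  counts <- base$counts$values
  gene_ids <- rownames(counts)
  J <- ncol(counts); I <- nrow(counts)
  labels <- base$truth$cell_labels
  ann <- synthetic_gene_annotation(gene_ids)
  tss <- vapply(ann, function(g) g$tss, numeric(1))
  # peaks: promoter (-1 kb) and distal (-10 kb) per gene, plus special cases
  peaks <- data.frame(
    chrom = "chr1",
    start = c(tss - 1200, tss - 10200),
    end = c(tss - 800, tss - 9800),
    name = c(paste0("chr1:", tss - 1200, "-", tss - 800),
             paste0("chr1:", tss - 10200, "-", tss - 9800)),
    role = rep(c("promoter", "distal"), each = I),
    gene = rep(gene_ids, 2), stringsAsFactors = FALSE)
  extra <- data.frame(
    chrom = "chr1",
    start = c(tss[1] + 151000, tss[2] + 200000, tss[3] + 100),
    end = c(tss[1] + 151400, tss[2] + 200400, tss[3] + 500),
    name = NA, role = c("far", "far", "exonic"),
    gene = gene_ids[c(1, 2, 3)], stringsAsFactors = FALSE)
  extra$name <- paste0("chr1:", extra$start, "-", extra$end)
  peaks <- rbind(peaks, extra)
  K <- nrow(peaks)
  # accessibility: background everywhere; DE-gene peaks open in their cluster
  acc_mu <- matrix(0.5, K, J)
  de_of <- integer(I)   # cluster owning each DE gene (0 = none)
  for (z in seq_along(base$truth$de_genes))
    de_of[match(base$truth$de_genes[[z]], gene_ids)] <- z
  for (k in seq_len(K)) {
    z <- de_of[match(peaks$gene[k], gene_ids)]
    if (z > 0) {
      acc_mu[k, labels == z] <- 6
      acc_mu[k, labels != z] <- 0.1
    } else {
      acc_mu[k, ] <- 2
    }
  }
  atac <- matrix(stats::rnbinom(K * J, mu = acc_mu, size = 2), K, J)
  rownames(atac) <- peaks$name; colnames(atac) <- colnames(counts)
  # velocity: a DE gene of cluster z sits at steady state in z (where its
  # expression is already high), is being induced (unspliced excess) in the
  # next cluster and repressed in the remaining ones -- so the steady-state
  # fit is anchored by the high-expression cells and the sign structure is
  # recoverable
  gamma <- stats::runif(I, 0.4, 0.8)
  spliced <- counts
  uns_mu <- gamma * (spliced + 0.5)
  vsign <- matrix(0L, I, J, dimnames = dimnames(counts))
  Z <- spec$n_clusters
  induced_m <- repressed_m <- matrix(FALSE, I, J)
  for (i in seq_len(I)) {
    if (de_of[i] > 0 && Z >= 2) {
      z <- de_of[i]
      induced <- labels == (z %% Z) + 1
      repressed <- !induced & labels != z
      uns_mu[i, induced] <- uns_mu[i, induced] * 3
      uns_mu[i, repressed] <- uns_mu[i, repressed] * 0.2
      induced_m[i, ] <- induced; repressed_m[i, ] <- repressed
    }
  }
  unspliced <- matrix(stats::rnbinom(I * J, mu = uns_mu, size = 5), I, J,
                      dimnames = dimnames(counts))
  # a sign is only planted where the realized counts can carry it: an
  # induced state needs unspliced transcripts, a repressed one spliced
  vsign[induced_m & unspliced > 0] <- 1L
  vsign[repressed_m & spliced > 0] <- -1L
  # motifs: planted TFs on promoter peaks of each cluster's DE genes
  motif_rows <- list()
  add_sites <- function(tf, genes, score) {
    pk <- peaks[peaks$role == "promoter" & peaks$gene %in% genes, ]
    data.frame(chrom = "chr1", start = pk$start + 100, end = pk$start + 110,
               name = tf, score = score, stringsAsFactors = FALSE)
  }
  regulon_map <- list()
  for (z in seq_along(base$truth$de_genes)[seq_len(min(spec$n_tfs,
                                               length(base$truth$de_genes)))]) {
    tf <- sprintf("TF_planted_%d", z)
    targets <- base$truth$de_genes[[z]]
    motif_rows[[tf]] <- add_sites(tf, targets, 900)
    regulon_map[[tf]] <- list(targets = targets, cluster = z)
  }
  non_de <- setdiff(gene_ids, unlist(base$truth$de_genes))
  for (t in seq_len(n_null_tfs)) {
    tf <- sprintf("TF_null_%02d", t)
    targets <- sample(non_de, min(8, length(non_de)))
    motif_rows[[tf]] <- add_sites(tf, targets, 700)
  }
  # sub-threshold sites that the affinity filter must drop
  motif_rows[["TF_weak"]] <- add_sites("TF_weak", gene_ids[1:3], 400)
  motifs <- do.call(rbind, motif_rows)
  rownames(motifs) <- NULL
  truth <- base$truth
  truth$regulon_map <- regulon_map
  truth$peak_gene_map <- peaks[, c("name", "gene", "role")]
  truth$velocity_sign_map <- vsign
  list(rna = base$counts,
       atac = named_matrix(atac, modality = "atac_peak"),
       spliced = named_matrix(spliced, modality = "rna"),
       unspliced = named_matrix(unspliced, modality = "rna"),
       peaks = peaks[, c("chrom", "start", "end", "name")],
       genes = ann, motifs = motifs, truth = truth)
}

#' Write a gene annotation list as GTF
#'
#' Emits gene and exon features with 1-based inclusive coordinates, the
#' inverse of the conversion applied on read.
#'
#' @param ann annotation list (as from [read_gene_annotation()] or
#'   [make_rna_atac()]).
#' @param path output path.
#' @export
write_gtf <- function(ann, path) {
  lines <- unlist(lapply(ann, function(g) {
    at <- sprintf('gene_id "%s";', g$gene_id)
    gene <- sprintf("%s\tsynthetic\tgene\t%d\t%d\t.\t%s\t.\t%s",
                    g$chrom, g$span[1] + 1, g$span[2], g$strand, at)
    ex <- sprintf("%s\tsynthetic\texon\t%d\t%d\t.\t%s\t.\t%s",
                  g$chrom, g$exons$start + 1, g$exons$end, g$strand, at)
    c(gene, ex)
  }))
  writeLines(lines, path)
  invisible(path)
}

#' Write a complete fixture directory
#'
#' Emits every file of a simulated dataset in the external formats the
#' readers accept (MTX triplets, BED, GTF, JSON truth).
#'
#' @param fix result of [make_rna()], [make_cite()] or [make_rna_atac()].
#' @param dir output directory (created).
#' @return the directory path.
#' @export
write_fixture <- function(fix, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wm <- function(m, stem) write_mtx_triplet(
    m, file.path(dir, paste0(stem, ".mtx")),
    file.path(dir, paste0(stem, ".rows.txt")),
    file.path(dir, paste0(stem, ".cols.txt")))
  for (nm in intersect(names(fix), c("counts", "rna", "atac", "protein",
                                     "spliced", "unspliced")))
    wm(fix[[nm]], nm)
  if (!is.null(fix$peaks)) write_bed(fix$peaks, file.path(dir, "peaks.bed"))
  if (!is.null(fix$genes)) write_gtf(fix$genes, file.path(dir, "genes.gtf"))
  if (!is.null(fix$motifs)) write_bed(fix$motifs,
                                      file.path(dir, "motifs.bed"))
  truth <- fix$truth
  truth$velocity_sign_map <- NULL     # large; regenerate from the spec
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE)
  invisible(dir)
}
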