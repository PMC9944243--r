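# shared helpers: tiny matrices and graphs built in code

toy_named_matrix <- function(values, modality = "rna",
                             rn = sprintf("g%d", seq_len(nrow(values))),
                             cn = sprintf("c%d", seq_len(ncol(values)))) {
  named_matrix(values, rn, cn, modality = modality)
}

# deterministic random count matrix
toy_counts <- function(n_genes = 20, n_cells = 15, seed = 1, lambda = 2) {
  set.seed(seed)
  m <- matrix(stats::rpois(n_genes * n_cells, lambda), n_genes, n_cells)
  toy_named_matrix(m)
}

# minimal gene annotation record (0-based half-open)
toy_gene <- function(gene_id, chrom = "chr1", strand = "+", exons) {
  exons <- exons[order(exons$start), , drop = FALSE]
  tss <- if (strand == "+") min(exons$start) else max(exons$end)
  list(gene_id = gene_id, chrom = chrom, strand = strand, tss = tss,
       exons = exons, span = c(min(exons$start), max(exons$end)),
       exon_length = sum(exons$end - exons$start))
}

toy_peaks <- function(starts, ends, chrom = "chr1",
                      names = paste0(chrom, ":", starts, "-", ends)) {
  data.frame(chrom = chrom, start = starts, end = ends, name = names,
             stringsAsFactors = FALSE)
}

# independent brute-force ARI by explicit pair counting over all item pairs
bruteforce_ari <- function(a, b) {
  n <- length(a)
  s11 <- s00 <- s10 <- s01 <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    same_a <- a[i] == a[j]; same_b <- b[i] == b[j]
    if (same_a && same_b) s11 <- s11 + 1
    else if (!same_a && !same_b) s00 <- s00 + 1
    else if (same_a) s10 <- s10 + 1
    else s01 <- s01 + 1
  }
  tot <- s11 + s00 + s10 + s01
  exp_idx <- (s11 + s10) * (s11 + s01) / tot
  max_idx <- ((s11 + s10) + (s11 + s01)) / 2
  if (max_idx == exp_idx) return(1)
  (s11 - exp_idx) / (max_idx - exp_idx)
}

# brute-force silhouette from the definition
bruteforce_asw <- function(D, labels) {
  n <- length(labels)
  mean(vapply(seq_len(n), function(j) {
    own <- setdiff(which(labels == labels[j]), j)
    if (!length(own)) return(0)
    m <- mean(D[j, own])
    nn <- min(vapply(setdiff(unique(labels), labels[j]),
                     function(k) mean(D[j, labels == k]), numeric(1)))
    (nn - m) / max(m, nn)
  }, numeric(1)))
}
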