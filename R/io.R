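#' Read a 10x-style MatrixMarket triplet into a named matrix
#'
#' @param matrix_path path to a MatrixMarket coordinate file.
#' @param row_names_path,col_names_path one identifier per line.
#' @param modality modality tag passed to [named_matrix()].
#' @return a \code{named_matrix}; entries absent from the coordinate section
#'   are zero.
#' @export
read_mtx_triplet <- function(matrix_path, row_names_path, col_names_path,
                             modality = "rna") {
  m <- Matrix::readMM(matrix_path)
  rn <- readLines(row_names_path)
  rn <- rn[nzchar(rn)]
  cn <- readLines(col_names_path)
  cn <- cn[nzchar(cn)]
  if (length(rn) != nrow(m) || length(cn) != ncol(m))
    stop("read_mtx_triplet: name count does not match matrix dimensions")
  named_matrix(as.matrix(m), rn, cn, modality = modality)
}

#' Write a named matrix as a MatrixMarket triplet plus name files
#'
#' @param m a \code{named_matrix}.
#' @param matrix_path,row_names_path,col_names_path output paths.
#' @export
write_mtx_triplet <- function(m, matrix_path, row_names_path, col_names_path) {
  Matrix::writeMM(Matrix::Matrix(m$values, sparse = TRUE), matrix_path)
  writeLines(rownames(m$values), row_names_path)
  writeLines(colnames(m$values), col_names_path)
  invisible(matrix_path)
}

#' Read a dense TSV matrix (header = cell barcodes, first column = features)
#'
#' @inheritParams read_mtx_triplet
#' @param path TSV path.
#' @return a \code{named_matrix}.
#' @export
read_dense_tsv <- function(path, modality = "rna") {
  df <- utils::read.table(path, header = TRUE, sep = "\t", row.names = 1,
                          check.names = FALSE)
  named_matrix(as.matrix(df), modality = modality)
}

#' Read BED3/BED5 intervals
#'
#' Coordinates are kept in BED's native 0-based half-open convention, the
#' internal convention of the whole package. A score is parsed from column 5
#' when present.
#'
#' @param path BED file (>= 3 tab-separated columns).
#' @return data.frame with columns chrom, start, end, name, score.
#' @export
read_bed <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "\t", fill = TRUE,
                          stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(df) < 3) stop("read_bed: need >= 3 columns")
  out <- data.frame(chrom = as.character(df[[1]]),
                    start = as.integer(df[[2]]),
                    end = as.integer(df[[3]]),
                    name = if (ncol(df) >= 4) as.character(df[[4]])
                           else paste0("iv", seq_len(nrow(df))),
                    score = if (ncol(df) >= 5) as.numeric(df[[5]]) else NA_real_,
                    stringsAsFactors = FALSE)
  if (any(out$start >= out$end))
    stop("read_bed: interval with start >= end")
  if (any(out$start < 0)) stop("read_bed: negative start")
  out
}

#' Write intervals as BED
#'
#' @param iv data.frame as returned by [read_bed()].
#' @param path output path.
#' @export
write_bed <- function(iv, path) {
  cols <- iv[, c("chrom", "start", "end", "name")]
  if (!all(is.na(iv$score))) cols$score <- iv$score
  utils::write.table(cols, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Convert 1-based closed (GTF/GRanges) coordinates to 0-based half-open
#'
#' @param start1,end1 integer vectors, 1-based inclusive.
#' @return list with \code{start} and \code{end}, 0-based half-open.
#' @export
gtf_to_zero_based <- function(start1, end1) {
  if (any(end1 < start1)) stop("gtf_to_zero_based: end < start")
  list(start = as.integer(start1 - 1L), end = as.integer(end1))
}

#' Read a gene annotation from GTF
#'
#' Parses exon features, merges overlapping exons per gene, and places the
#' TSS at the start of the first exon (+ strand) or the end of the last exon
#' (- strand). Coordinates are converted to the internal 0-based half-open
#' convention. Genes without exons are dropped with a warning.
#'
#' @param path GTF file with exon features carrying \code{gene_id}.
#' @return list of gene records: \code{gene_id}, \code{chrom}, \code{strand},
#'   \code{tss} (0-based position), \code{exons} (data.frame start/end,
#'   0-based half-open), \code{span} (transcript span, 0-based half-open),
#'   \code{exon_length}.
#' @export
read_gene_annotation <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  feat <- as.character(gr$type)
  has_gene <- which(feat == "gene")
  ex <- gr[feat == "exon"]
  if (length(ex) == 0) stop("read_gene_annotation: no exon features")
  gene_ids <- unique(as.character(gr$gene_id))
  gene_ids <- gene_ids[!is.na(gene_ids)]
  exl <- split(ex, as.character(ex$gene_id))
  dropped <- setdiff(gene_ids, names(exl))
  if (length(dropped))
    warning("read_gene_annotation: dropping genes with no exon: ",
            paste(dropped, collapse = ", "))
  ann <- lapply(names(exl), function(g) {
    e <- GenomicRanges::reduce(exl[[g]])
    chrom <- as.character(GenomicRanges::seqnames(e))[1]
    strand <- as.character(GenomicRanges::strand(e))[1]
    if (!strand %in% c("+", "-")) strand <- "+"
    z <- gtf_to_zero_based(GenomicRanges::start(e), GenomicRanges::end(e))
    exons <- data.frame(start = z$start, end = z$end)
    exons <- exons[order(exons$start), , drop = FALSE]
    tss <- if (strand == "+") min(exons$start) else max(exons$end)
    list(gene_id = g, chrom = chrom, strand = strand, tss = tss,
         exons = exons, span = c(min(exons$start), max(exons$end)),
         exon_length = sum(exons$end - exons$start))
  })
  names(ann) <- names(exl)
  ann
}

#' Parse peak identifiers of the form "chr1:100-200" or "chr1-100-200"
#'
#' @param ids character vector of peak names.
#' @return data.frame chrom/start/end/name (0-based half-open, as written).
#' @export
parse_peak_ids <- function(ids) {
  colon <- grepl(":", ids, fixed = TRUE)
  chrom <- character(length(ids)); start <- integer(length(ids))
  end <- integer(length(ids))
  for (i in seq_along(ids)) {
    if (colon[i]) {
      parts <- strsplit(ids[i], "[:-]")[[1]]
    } else {
      # "chr1-100-200": split on '-' keeping the chrom prefix intact
      parts <- strsplit(ids[i], "-")[[1]]
      if (length(parts) > 3)
        parts <- c(paste(parts[1:(length(parts) - 2)], collapse = "-"),
                   parts[length(parts) - 1], parts[length(parts)])
    }
    if (length(parts) != 3 || is.na(suppressWarnings(as.integer(parts[2]))))
      stop("parse_peak_ids: cannot parse '", ids[i], "'")
    chrom[i] <- parts[1]
    start[i] <- as.integer(parts[2])
    end[i] <- as.integer(parts[3])
  }
  if (any(start >= end)) stop("parse_peak_ids: start >= end")
  data.frame(chrom = chrom, start = start, end = end, name = ids,
             stringsAsFactors = FALSE)
}

#' Write / read a weighted edge list as TSV
#'
#' Rows are ordered lexicographically by (from, to) so output is
#' deterministic; weights keep full double precision and round-trip within
#' 1e-6.
#'
#' @param edges data.frame with columns from, to, weight.
#' @param path output path.
#' @export
write_edge_list <- function(edges, path) {
  stopifnot(all(c("from", "to", "weight") %in% names(edges)))
  edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  utils::write.table(format(edges, digits = 15, scientific = FALSE,
                            trim = TRUE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_edge_list
#' @export
read_edge_list <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  df$weight <- as.numeric(df$weight)
  df
}

#' Write / read cluster labels as TSV (barcode, cluster)
#'
#' @param labeling a \code{cluster_labeling} (see [louvain_cluster()]) or a
#'   named vector of cluster ids.
#' @param path output path.
#' @export
write_labels <- function(labeling, path) {
  if (inherits(labeling, "cluster_labeling")) labeling <- labeling$assignment
  df <- data.frame(barcode = names(labeling),
                   cluster = as.integer(labeling))
  df <- df[order(df$barcode), , drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_labels
#' @export
read_labels <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  stats::setNames(as.integer(df$cluster), df$barcode)
}
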