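#' Construct a named feature-by-cell matrix
#'
#' The single internal currency for all pipeline stages: a dense base matrix
#' with unique row names (genes / proteins / peaks), unique column names
#' (cell barcodes) and a modality tag. Count-like modalities must be
#' non-negative; \code{"velocity"} may carry any real value.
#'
#' @param values numeric matrix (features x cells).
#' @param row_names,col_names character vectors; taken from \code{dimnames(values)}
#'   when omitted.
#' @param modality one of \code{"rna"}, \code{"protein"}, \code{"atac_peak"},
#'   \code{"velocity"}, \code{"gas"}.
#' @return a \code{named_matrix} object.
#' @export
named_matrix <- function(values, row_names = rownames(values),
                         col_names = colnames(values),
                         modality = c("rna", "protein", "atac_peak",
                                      "velocity", "gas")) {
  modality <- match.arg(modality)
  values <- as.matrix(values)
  if (is.null(row_names) || is.null(col_names))
    stop("named_matrix: row and column names are required")
  row_names <- as.character(row_names)
  col_names <- as.character(col_names)
  if (length(row_names) != nrow(values) || length(col_names) != ncol(values))
    stop("named_matrix: dimension/name-count mismatch")
  if (anyDuplicated(row_names))
    stop("named_matrix: duplicate row names")
  if (anyDuplicated(col_names))
    stop("named_matrix: duplicate column names")
  if (anyNA(values) || any(!is.finite(values)))
    stop("named_matrix: values must be finite")
  if (modality != "velocity" && any(values < 0))
    stop("named_matrix: negative values in modality '", modality, "'")
  dimnames(values) <- list(row_names, col_names)
  structure(list(values = values, modality = modality),
            class = "named_matrix")
}

#' @export
print.named_matrix <- function(x, ...) {
  cat(sprintf("<named_matrix> %d x %d, modality '%s'\n",
              nrow(x$values), ncol(x$values), x$modality))
  invisible(x)
}

#' @export
dim.named_matrix <- function(x) dim(x$values)

#' @rdname named_matrix
#' @param x a \code{named_matrix}.
#' @export
nm_values <- function(x) {
  stopifnot(inherits(x, "named_matrix"))
  x$values
}

#' Subset a named matrix by row/column names or indices
#'
#' @param x a \code{named_matrix}.
#' @param rows,cols index or name vectors; \code{NULL} keeps all.
#' @return a \code{named_matrix} of the same modality.
#' @export
nm_subset <- function(x, rows = NULL, cols = NULL) {
  v <- x$values
  if (!is.null(rows)) v <- v[rows, , drop = FALSE]
  if (!is.null(cols)) v <- v[, cols, drop = FALSE]
  named_matrix(v, modality = x$modality)
}

# internal: replace values, keep names/modality
nm_replace <- function(x, values) {
  dimnames(values) <- dimnames(x$values)
  x$values <- values
  x
}
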