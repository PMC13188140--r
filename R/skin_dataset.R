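as_sparse_counts <- function(m) {
  if (!inherits(m, "sparseMatrix")) m <- Matrix::Matrix(m, sparse = TRUE)
  m <- methods::as(methods::as(m, "CsparseMatrix"), "generalMatrix")
  if (!methods::is(m, "dMatrix")) m <- methods::as(m, "dMatrix")  # pattern/logical input
  m
}

#' Binned spatial expression dataset
#'
#' Light container pairing a genes x bins sparse count matrix with its per-bin
#' metadata table. All pipeline verbs (`compute_qc_metrics()`, `apply_qc()`,
#' `normalize_counts()`, `assign_layers()`, ...) take a `skin_dataset` first
#' and return one, so stages chain with the pipe; tabular results
#' (densities, compositions, DE tables) come out as tibbles.
#'
#' @param counts A genes x bins sparse or dense matrix of non-negative integer
#'   counts with unique rownames (gene names) and colnames (bin barcodes).
#' @param bins A data frame with one row per bin, in matrix column order,
#'   containing at least `barcode`, `in_tissue` (0/1), `array_row`,
#'   `array_col`, `pxl_row`, `pxl_col`, `section_id`, `condition`.
#' @param bin_edge_um Edge length of a square bin in micrometres. The default
#'   16 matches the binned resolution the downstream area constant
#'   (0.000256 mm^2 per bin) assumes.
#'
#' @return An object of class `skin_dataset`: a list with elements `counts`
#'   (dgCMatrix), `bins` (tibble), `bin_edge_um`, and after normalization
#'   `norm` and `scale_factor`.
#' @export
skin_dataset <- function(counts, bins, bin_edge_um = 16) {
  counts <- as_sparse_counts(counts)
  bins <- tibble::as_tibble(bins)
  if ((is.null(rownames(counts)) && nrow(counts) > 0) ||
      (is.null(colnames(counts)) && ncol(counts) > 0)) {
    stop("counts must have gene rownames and barcode colnames", call. = FALSE)
  }
  if (is.null(rownames(counts))) rownames(counts) <- character(0)
  if (is.null(colnames(counts))) colnames(counts) <- character(0)
  if (anyDuplicated(rownames(counts))) stop("duplicate gene names", call. = FALSE)
  if (anyDuplicated(colnames(counts))) stop("duplicate bin barcodes", call. = FALSE)
  if (!"barcode" %in% names(bins)) stop("bins must have a 'barcode' column", call. = FALSE)
  if (anyDuplicated(bins$barcode)) stop("duplicate barcodes in bin table", call. = FALSE)
  if (ncol(counts) != nrow(bins)) {
    stop(sprintf("dimension mismatch: %d matrix columns but %d bin rows",
                 ncol(counts), nrow(bins)), call. = FALSE)
  }
  if (!identical(colnames(counts), bins$barcode)) {
    if (!setequal(colnames(counts), bins$barcode)) {
      stop("matrix barcodes and bin-table barcodes disagree", call. = FALSE)
    }
    bins <- bins[match(colnames(counts), bins$barcode), ]
  }
  if (length(counts@x) && min(counts@x) < 0) stop("negative counts", call. = FALSE)
  if (!is.numeric(bin_edge_um) || bin_edge_um <= 0) {
    stop("bin_edge_um must be a positive number", call. = FALSE)
  }
  structure(
    list(counts = counts, bins = bins, bin_edge_um = as.numeric(bin_edge_um),
         norm = NULL, scale_factor = NULL, meta = list()),
    class = "skin_dataset"
  )
}

#' @export
print.skin_dataset <- function(x, ...) {
  cat(sprintf("<skin_dataset> %d genes x %d bins (%g um bins)\n",
              nrow(x$counts), ncol(x$counts), x$bin_edge_um))
  if (!is.null(x$norm)) cat(sprintf("  normalized (scale factor %g)\n", x$scale_factor))
  conds <- unique(x$bins$condition)
  secs <- unique(x$bins$section_id)
  cat(sprintf("  conditions: %s | sections: %s\n",
              paste(conds, collapse = ", "), paste(secs, collapse = ", ")))
  invisible(x)
}

#' @export
dim.skin_dataset <- function(x) dim(x$counts)

#' Gene names of a dataset
#' @param x A `skin_dataset`.
#' @return Character vector of gene names.
#' @export
gene_names <- function(x) rownames(x$counts)
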