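#' Per-bin mitochondrial count percentage
#'
#' Percentage of each bin's total counts coming from mitochondrially encoded
#' genes, identified by the exact, case-sensitive name prefix `"MT-"`.
#' Bins with zero total counts are assigned 0 by convention (they are
#' removed later by the `n_count > 0` retention rule).
#'
#' @param counts A genes x bins matrix with gene rownames, or a
#'   `skin_dataset` (its counts are used).
#' @return Numeric vector, one percentage in \[0, 100\] per bin.
#' @export
compute_percent_mt <- function(counts) {
  if (inherits(counts, "skin_dataset")) counts <- counts$counts
  total <- Matrix::colSums(counts)
  mt <- startsWith(rownames(counts), "MT-")
  mt_total <- if (any(mt)) Matrix::colSums(counts[mt, , drop = FALSE]) else
    rep(0, ncol(counts))
  unname(ifelse(total > 0, 100 * mt_total / total, 0))
}

#' Populate per-bin QC statistics
#'
#' Adds `n_count` (total UMIs), `n_feature` (genes detected) and
#' `percent_mt` to the bin table.
#'
#' @param dataset A `skin_dataset`.
#' @return The dataset with QC columns populated.
#' @export
compute_qc_metrics <- function(dataset) {
  stopifnot(inherits(dataset, "skin_dataset"))
  dataset$bins$n_count <- Matrix::colSums(dataset$counts)
  dataset$bins$n_feature <- Matrix::colSums(dataset$counts > 0)
  dataset$bins$percent_mt <- compute_percent_mt(dataset$counts)
  dataset
}

#' Bin retention thresholds
#'
#' The retention rule keeps a bin only if it lies in tissue
#' (`in_tissue = 1`), has strictly positive total counts and detected
#' genes, and has mitochondrial content strictly below
#' `max_percent_mt_exclusive` percent (default 15; a bin at exactly 15% is
#' excluded).
#'
#' @param require_in_tissue Keep only `in_tissue = 1` bins (default TRUE).
#' @param min_count_exclusive,min_feature_exclusive Exclusive lower bounds
#'   on total counts and detected genes (defaults 0, i.e. `> 0`).
#' @param max_percent_mt_exclusive Exclusive upper bound on percent.mt, in
#'   (0, 100\].
#' @return A list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(require_in_tissue = TRUE,
                          min_count_exclusive = 0,
                          min_feature_exclusive = 0,
                          max_percent_mt_exclusive = 15.0) {
  if (!(max_percent_mt_exclusive > 0 && max_percent_mt_exclusive <= 100)) {
    stop("max_percent_mt_exclusive must lie in (0, 100]", call. = FALSE)
  }
  structure(list(require_in_tissue = isTRUE(require_in_tissue),
                 min_count_exclusive = min_count_exclusive,
                 min_feature_exclusive = min_feature_exclusive,
                 max_percent_mt_exclusive = max_percent_mt_exclusive),
            class = "qc_thresholds")
}

#' Apply bin-level quality control
#'
#' Retains bins satisfying all four criteria (strict inequalities
#' throughout): in tissue, `n_count > 0`, `n_feature > 0`, and
#' `percent_mt < max`. Bins whose normalized column would be all-zero are
#' removed in the same pass (under a positivity-preserving transform these
#' are exactly the zero-count bins, already caught by `n_count > 0`), after
#' which QC statistics are recomputed — so the operation is idempotent. The
#' per-bin pass/fail audit is attached as attribute `"qc_report"` and the
#' pre-QC in-tissue bin tally per section is kept in `dataset$meta` for the
#' optional in-tissue area denominator.
#'
#' @param dataset A `skin_dataset`; QC columns are computed if absent.
#' @param thresholds A [qc_thresholds()].
#' @return The filtered dataset.
#' @export
apply_qc <- function(dataset, thresholds = qc_thresholds()) {
  stopifnot(inherits(dataset, "skin_dataset"), inherits(thresholds, "qc_thresholds"))
  if (!"percent_mt" %in% names(dataset$bins)) dataset <- compute_qc_metrics(dataset)
  b <- dataset$bins
  pass_tissue <- if (thresholds$require_in_tissue) b$in_tissue == 1L else TRUE
  pass_count <- b$n_count > thresholds$min_count_exclusive
  pass_feature <- b$n_feature > thresholds$min_feature_exclusive
  pass_mt <- b$percent_mt < thresholds$max_percent_mt_exclusive
  keep <- pass_tissue & pass_count & pass_feature & pass_mt

  report <- tibble::tibble(
    barcode = b$barcode,
    in_tissue_ok = as.logical(pass_tissue & rep(TRUE, nrow(b))),
    count_ok = pass_count, feature_ok = pass_feature, percent_mt_ok = pass_mt,
    retained = keep,
    reason = dplyr::case_when(
      keep ~ "retained",
      !(pass_tissue & rep(TRUE, nrow(b))) ~ "not_in_tissue",
      !pass_count ~ "zero_counts",
      !pass_feature ~ "zero_features",
      TRUE ~ "high_percent_mt"
    )
  )

  if (is.null(dataset$meta$in_tissue_bins)) {
    dataset$meta$in_tissue_bins <- b |>
      dplyr::filter(.data$in_tissue == 1L) |>
      dplyr::count(.data$section_id, .data$condition, name = "n_in_tissue")
  }

  out <- dataset
  out$counts <- dataset$counts[, keep, drop = FALSE]
  out$bins <- b[keep, , drop = FALSE]
  # one-shot removal of bins with an all-zero normalized column, then refresh
  nz <- Matrix::colSums(out$counts) > 0
  if (!all(nz)) {
    out$counts <- out$counts[, nz, drop = FALSE]
    out$bins <- out$bins[nz, , drop = FALSE]
  }
  out <- compute_qc_metrics(out)
  if (!is.null(dataset$norm)) out <- normalize_counts(out, dataset$scale_factor)
  attr(out, "qc_report") <- report
  out
}

#' Depth-scaled log normalization
#'
#' Transforms each count c in a bin with total t to
#' `ln(1 + scale_factor * c / t)`. The transform is monotone within a bin
#' and maps zero to zero and only zero to zero, so an entry is positive in
#' the normalized matrix exactly when the raw count is — the property the
#' downstream gene-positive-bin metrics rely on. It also depends on counts
#' only through within-bin proportions, so per-bin sequencing depth cancels.
#'
#' @param dataset A `skin_dataset` whose bins all have positive totals
#'   (apply [apply_qc()] first).
#' @param scale_factor Positive scale constant (default 10,000).
#' @return The dataset with `norm` (dgCMatrix) and `scale_factor` set.
#' @export
normalize_counts <- function(dataset, scale_factor = 1e4) {
  stopifnot(inherits(dataset, "skin_dataset"))
  if (!is.numeric(scale_factor) || scale_factor <= 0) {
    stop("scale_factor must be positive", call. = FALSE)
  }
  totals <- Matrix::colSums(dataset$counts)
  if (any(totals == 0)) {
    stop("bins with zero total counts present; run apply_qc() first", call. = FALSE)
  }
  norm <- dataset$counts
  if (length(norm@x)) {
    col_of_x <- rep.int(seq_len(ncol(norm)), diff(norm@p))
    norm@x <- log1p(scale_factor * norm@x / totals[col_of_x])
  }
  dataset$norm <- norm
  dataset$scale_factor <- scale_factor
  dataset
}

#' QC audit report of the last [apply_qc()] call
#' @param dataset A dataset returned by [apply_qc()].
#' @return Tibble with one row per input bin: the four criteria, retention
#'   flag, and failure reason.
#' @export
qc_report <- function(dataset) {
  rep <- attr(dataset, "qc_report")
  if (is.null(rep)) stop("no QC report: run apply_qc() first", call. = FALSE)
  rep
}
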