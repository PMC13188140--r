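#' Senescence / DNA-damage gene panel
#'
#' Default panel of ten transcripts induced by UV stress in aged skin:
#' CDKN1A (p21), CRYAB, DST, EZR, FTL, HMOX1, KRT6A, S100A2, S100A16 and
#' ZFP36.
#'
#' @param genes Character vector of gene names; must be non-empty.
#' @return Character vector classed `senescence_panel`.
#' @export
senescence_panel <- function(genes = c("CDKN1A", "CRYAB", "DST", "EZR", "FTL",
                                       "HMOX1", "KRT6A", "S100A2", "S100A16",
                                       "ZFP36")) {
  genes <- as.character(genes)
  if (!length(genes)) stop("senescence panel must be non-empty", call. = FALSE)
  structure(genes, class = c("senescence_panel", "character"))
}

#' Number of gene-positive bins
#'
#' A bin is positive for a gene when its normalized expression is strictly
#' greater than zero — under the positivity-preserving normalization this
#' is exactly the bins with raw count >= 1. Counting is over the bins
#' currently in the dataset (i.e. the QC-passing in-tissue bins).
#'
#' @param dataset A normalized `skin_dataset`.
#' @param gene Gene name.
#' @return Integer count of positive bins.
#' @export
positive_bins <- function(dataset, gene) {
  stopifnot(inherits(dataset, "skin_dataset"))
  mat <- dataset$norm %||% dataset$counts
  if (!gene %in% rownames(mat)) stop("unknown gene: ", gene, call. = FALSE)
  sum(mat[gene, ] > 0)
}

#' Tissue area covered by a number of bins
#'
#' `n_bins * (bin_edge_um / 1000)^2` square millimetres; at the default
#' 16 um bin edge one bin covers 0.000256 mm^2.
#'
#' @param n_bins Number of bins (>= 0).
#' @param bin_edge_um Bin edge length in micrometres (> 0).
#' @return Area in mm^2.
#' @export
tissue_area <- function(n_bins, bin_edge_um = 16) {
  if (any(n_bins < 0)) stop("negative bin count", call. = FALSE)
  if (any(bin_edge_um <= 0)) stop("bin_edge_um must be positive", call. = FALSE)
  n_bins * (bin_edge_um / 1000)^2
}

#' Positive-bin density per mm^2
#' @param n_positive Number of positive bins.
#' @param area_mm2 Tissue area in mm^2 (> 0).
#' @return Density in bins per mm^2.
#' @export
positive_density <- function(n_positive, area_mm2) {
  if (any(area_mm2 <= 0)) stop("tissue area must be positive", call. = FALSE)
  n_positive / area_mm2
}

#' Per-section positive-bin metrics for a gene panel
#'
#' For each gene x section: the number of positive bins, the number of
#' tissue bins, the tissue area and the density. The area denominator uses
#' the bins present in the dataset (QC-passing) by default, or the pre-QC
#' in-tissue tally recorded by [apply_qc()] when
#' `area_population = "in_tissue"`.
#'
#' @param dataset A normalized, QC'd, merged `skin_dataset`.
#' @param genes Gene names (default the [senescence_panel()]).
#' @param area_population `"qc_passed"` (default) or `"in_tissue"`.
#' @return Tibble: gene, condition, section_id, n_positive_bins,
#'   n_tissue_bins, tissue_area_mm2, density_per_mm2.
#' @export
density_by_section <- function(dataset, genes = senescence_panel(),
                               area_population = c("qc_passed", "in_tissue")) {
  stopifnot(inherits(dataset, "skin_dataset"))
  area_population <- match.arg(area_population)
  genes <- as.character(genes)
  mat <- dataset$norm %||% dataset$counts
  absent <- setdiff(genes, rownames(mat))
  if (length(absent)) {
    stop("gene(s) missing from dataset: ", paste(absent, collapse = ", "),
         call. = FALSE)
  }
  pos <- mat[genes, , drop = FALSE] > 0
  secs <- dataset$bins |>
    dplyr::distinct(.data$section_id, .data$condition)
  denom <- if (area_population == "in_tissue") {
    if (is.null(dataset$meta$in_tissue_bins)) {
      stop("in_tissue denominator unavailable: dataset has no pre-QC tally ",
           "(run apply_qc() on the unfiltered data)", call. = FALSE)
    }
    dataset$meta$in_tissue_bins |> dplyr::rename(n_tissue_bins = "n_in_tissue")
  } else {
    dataset$bins |> dplyr::count(.data$section_id, .data$condition,
                                 name = "n_tissue_bins")
  }
  purrr::map_dfr(seq_len(nrow(secs)), function(i) {
    sel <- dataset$bins$section_id == secs$section_id[i]
    tibble::tibble(
      gene = genes,
      condition = secs$condition[i],
      section_id = secs$section_id[i],
      n_positive_bins = as.integer(Matrix::rowSums(pos[, sel, drop = FALSE]))
    )
  }) |>
    dplyr::left_join(denom, by = c("section_id", "condition")) |>
    dplyr::mutate(
      tissue_area_mm2 = tissue_area(.data$n_tissue_bins, dataset$bin_edge_um),
      density_per_mm2 = .data$n_positive_bins / .data$tissue_area_mm2
    )
}

#' Pool per-section metrics to condition level
#'
#' Pools spatial bins across the sections of a condition: positive-bin
#' counts, tissue-bin counts and areas are summed first and the density is
#' the ratio of the sums (not the mean of per-section densities).
#'
#' @param section_stats Output of [density_by_section()].
#' @return Tibble: gene, condition, n_positive_bins, n_tissue_bins,
#'   tissue_area_mm2, density_per_mm2, n_sections.
#' @export
pool_by_condition <- function(section_stats) {
  if (!nrow(section_stats)) stop("no section metrics to pool", call. = FALSE)
  section_stats |>
    dplyr::group_by(.data$gene, .data$condition) |>
    dplyr::summarise(
      n_positive_bins = sum(.data$n_positive_bins),
      n_tissue_bins = sum(.data$n_tissue_bins),
      tissue_area_mm2 = sum(.data$tissue_area_mm2),
      n_sections = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(density_per_mm2 = .data$n_positive_bins / .data$tissue_area_mm2)
}

#' Condition-level positive-bin counts and densities
#'
#' Convenience wrapper: per-section metrics via [density_by_section()],
#' pooled to condition level via [pool_by_condition()]. The per-section
#' table is attached as attribute `"per_section"`.
#'
#' @inheritParams density_by_section
#' @return Pooled tibble (see [pool_by_condition()]).
#' @export
density_by_condition <- function(dataset, genes = senescence_panel(),
                                 area_population = c("qc_passed", "in_tissue")) {
  per_sec <- density_by_section(dataset, genes, area_population)
  out <- pool_by_condition(per_sec)
  attr(out, "per_section") <- per_sec
  out
}

#' Directional consistency of a density difference across section pairs
#'
#' A constructed statistic formalizing cross-section agreement: for each
#' gene, over all cross pairs (section of condition a) x (section of
#' condition b), the fraction of pairs whose per-section density difference
#' has the same sign as the pooled (condition-level) difference. `sign(0)`
#' agrees only with 0. Undefined (NA) when a condition has no sections.
#'
#' @param section_stats Output of [density_by_section()].
#' @param condition_a,condition_b Condition labels to compare (a minus b).
#' @return Tibble: gene, pooled_difference, n_pairs, consistency.
#' @export
directional_consistency <- function(section_stats, condition_a, condition_b) {
  sa <- section_stats |> dplyr::filter(.data$condition == condition_a)
  sb <- section_stats |> dplyr::filter(.data$condition == condition_b)
  if (!nrow(sa) || !nrow(sb)) {
    stop("both conditions need at least one section", call. = FALSE)
  }
  pooled <- pool_by_condition(dplyr::bind_rows(sa, sb)) |>
    dplyr::select("gene", "condition", "density_per_mm2") |>
    tidyr::pivot_wider(names_from = "condition", values_from = "density_per_mm2")
  purrr::map_dfr(unique(section_stats$gene), function(g) {
    da <- sa$density_per_mm2[sa$gene == g]
    db <- sb$density_per_mm2[sb$gene == g]
    pd <- pooled[[condition_a]][pooled$gene == g] -
      pooled[[condition_b]][pooled$gene == g]
    pairs <- outer(da, db, `-`)
    agree <- sign(pairs) == sign(pd)
    tibble::tibble(gene = g, pooled_difference = pd,
                   n_pairs = length(pairs),
                   consistency = mean(agree))
  })
}

#' Bar plot of pooled positive-bin density per gene and condition
#' @param density Output of [density_by_condition()] or [pool_by_condition()].
#' @param metric Column to plot (`"density_per_mm2"` or `"n_positive_bins"`).
#' @return A ggplot object.
#' @export
plot_density_bars <- function(density, metric = "density_per_mm2") {
  ggplot2::ggplot(density,
                  ggplot2::aes(x = .data$gene, y = .data[[metric]],
                               fill = .data$condition)) +
    ggplot2::geom_col(position = ggplot2::position_dodge()) +
    ggplot2::labs(x = NULL, y = metric, fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
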