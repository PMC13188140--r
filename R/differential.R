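#' Two-sided Wilcoxon rank-sum test
#'
#' Exact p-value by enumeration when the pooled sample has at most 10
#' observations and no ties; otherwise the tie-corrected normal
#' approximation with continuity correction. Both routes are the standard
#' implementations in [stats::wilcox.test()]; this wrapper pins the
#' exactness rule.
#'
#' @param x,y Numeric value vectors for the two groups; both non-empty.
#' @return List with `statistic` (Mann-Whitney U for the first group) and
#'   `p_value` (two-sided).
#' @export
rank_sum_test <- function(x, y) {
  if (!length(x) || !length(y)) stop("both groups must be non-empty", call. = FALSE)
  ties <- anyDuplicated(c(x, y)) > 0
  use_exact <- (length(x) + length(y)) <= 10 && !ties
  res <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided",
                       exact = use_exact, correct = TRUE)
  )
  list(statistic = unname(res$statistic), p_value = res$p.value)
}

#' Benjamini-Hochberg (or Bonferroni) p-value adjustment
#'
#' Step-up BH with monotonicity enforcement, capped at 1, via
#' [stats::p.adjust()].
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @param method `"BH"` (default) or `"bonferroni"`.
#' @return Adjusted p-values, same order as the input.
#' @export
bh_adjust <- function(p, method = c("BH", "bonferroni")) {
  method <- match.arg(method)
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = method)
}

#' Pairwise differential expression between two bin groups
#'
#' Rank-sum DE on the normalized matrix, following the conventional
#' marker-finding contract: mitochondrial ("MT-"-prefixed) genes are
#' excluded before testing; a gene is tested only if it is detected in at
#' least `min_pct` of the bins of either group and its absolute log2 fold
#' change reaches `logfc_threshold` (only positive-fold genes when
#' `only_pos`). The log2 fold change is
#' `log2((mean(expm1(norm_1)) + eps) / (mean(expm1(norm_2)) + eps))` with
#' `eps = 1e-9`; detection fractions `pct_1`/`pct_2` are the fractions of
#' bins with positive expression. Adjustment is applied over the tested
#' genes only.
#'
#' @param dataset A normalized `skin_dataset`.
#' @param group_1,group_2 Values of `group_col` defining the two disjoint
#'   bin groups (group 1 vs group 2).
#' @param group_col Bin-table column holding group labels (default
#'   `"condition"`).
#' @param min_pct Minimum detection fraction in the better-detected group
#'   (default 0.01).
#' @param logfc_threshold Minimum |log2 fold change| (default 0).
#' @param only_pos Keep only genes up in group 1 (default FALSE).
#' @param p_adjust Adjustment method, `"BH"` (default) or `"bonferroni"`.
#' @return Tibble of class `skin_de`: gene, p_value, p_adjusted, log2_fc,
#'   pct_1, pct_2, n_1, n_2, ordered by p-value.
#' @export
find_markers <- function(dataset, group_1, group_2, group_col = "condition",
                         min_pct = 0.01, logfc_threshold = 0,
                         only_pos = FALSE, p_adjust = c("BH", "bonferroni")) {
  stopifnot(inherits(dataset, "skin_dataset"))
  p_adjust <- match.arg(p_adjust)
  if (is.null(dataset$norm)) stop("normalize_counts() must be run first", call. = FALSE)
  labels <- dataset$bins[[group_col]]
  if (is.null(labels)) stop("unknown grouping column: ", group_col, call. = FALSE)
  i1 <- which(labels %in% group_1)
  i2 <- which(labels %in% group_2)
  if (!length(i1)) stop("unknown or empty group label: ", paste(group_1, collapse = ","), call. = FALSE)
  if (!length(i2)) stop("unknown or empty group label: ", paste(group_2, collapse = ","), call. = FALSE)
  if (length(intersect(i1, i2))) stop("groups overlap", call. = FALSE)

  keep_genes <- !startsWith(rownames(dataset$norm), "MT-")
  m1 <- dataset$norm[keep_genes, i1, drop = FALSE]
  m2 <- dataset$norm[keep_genes, i2, drop = FALSE]
  eps <- 1e-9
  pct_1 <- Matrix::rowSums(m1 > 0) / length(i1)
  pct_2 <- Matrix::rowSums(m2 > 0) / length(i2)
  log2_fc <- log2((Matrix::rowMeans(expm1_sparse(m1)) + eps) /
                  (Matrix::rowMeans(expm1_sparse(m2)) + eps))
  tested <- pmax(pct_1, pct_2) >= min_pct & abs(log2_fc) >= logfc_threshold
  if (only_pos) tested <- tested & log2_fc > 0

  genes <- rownames(m1)[tested]
  pv <- vapply(genes, function(g) {
    rank_sum_test(as.numeric(m1[g, ]), as.numeric(m2[g, ]))$p_value
  }, numeric(1))
  out <- tibble::tibble(
    gene = genes,
    p_value = unname(pv),
    p_adjusted = bh_adjust(unname(pv), method = p_adjust),
    log2_fc = unname(log2_fc[tested]),
    pct_1 = unname(pct_1[tested]),
    pct_2 = unname(pct_2[tested]),
    n_1 = length(i1), n_2 = length(i2)
  ) |>
    dplyr::arrange(.data$p_value, .data$gene)
  class(out) <- c("skin_de", class(out))
  out
}

expm1_sparse <- function(m) {
  m@x <- expm1(m@x)
  m
}

#' Volcano-style plot of a DE table
#' @param object A `skin_de` tibble from [find_markers()].
#' @param alpha Adjusted-p significance threshold to color by.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot skin_de
#' @export
autoplot.skin_de <- function(object, alpha = 0.05, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$log2_fc,
                               y = -log10(pmax(.data$p_adjusted, 1e-300)),
                               colour = .data$p_adjusted < alpha)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(x = "log2 fold change", y = "-log10 adjusted p",
                  colour = sprintf("adj. p < %g", alpha)) +
    ggplot2::theme_minimal()
}
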