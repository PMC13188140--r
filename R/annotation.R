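#' Epidermal / dermal marker panel
#'
#' Maps layer labels to canonical marker genes: basal cells (BC) by TP63,
#' spinous cells (SC) by KRT10 and KRTDAP, granular cells (GC) by FLG, and
#' fibroblasts (FB) by COL1A1 and TIMP1. Labels and gene sets must be
#' non-empty and a gene may belong to only one label.
#'
#' @param panel Named list mapping label to a character vector of genes.
#' @return The validated panel, classed `marker_panel`.
#' @export
marker_panel <- function(panel = list(BC = "TP63",
                                      SC = c("KRT10", "KRTDAP"),
                                      GC = "FLG",
                                      FB = c("COL1A1", "TIMP1"))) {
  if (!length(panel) || is.null(names(panel)) || any(!nzchar(names(panel)))) {
    stop("marker panel labels must be non-empty", call. = FALSE)
  }
  if (any(lengths(panel) == 0)) stop("marker gene sets must be non-empty", call. = FALSE)
  genes <- unlist(panel, use.names = FALSE)
  if (anyDuplicated(genes)) {
    stop("a marker gene may appear under only one label: ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "), call. = FALSE)
  }
  structure(panel, class = "marker_panel")
}

#' Read a marker panel from a YAML file (`label: [genes]`)
#' @param path Path to a YAML mapping of label to gene list.
#' @return A [marker_panel()].
#' @export
read_marker_panel <- function(path) {
  marker_panel(lapply(yaml::read_yaml(path), as.character))
}

#' Per-bin marker scores for each layer label
#'
#' For each tissue section separately, each marker gene's normalized
#' expression is z-scaled across the section's bins (sample-sd convention;
#' zero-variance genes contribute 0), and a label's score for a bin is the
#' mean z-score over the label's genes. Scaling within a section keeps the
#' scores comparable when sections differ in depth.
#'
#' @param dataset A normalized `skin_dataset`.
#' @param panel A [marker_panel()].
#' @return Tibble: barcode, section_id, then one score column per label.
#' @export
marker_scores <- function(dataset, panel = marker_panel()) {
  stopifnot(inherits(dataset, "skin_dataset"))
  if (is.null(dataset$norm)) stop("normalize_counts() must be run first", call. = FALSE)
  panel <- marker_panel(unclass(panel))
  genes <- unlist(panel, use.names = FALSE)
  absent <- setdiff(genes, rownames(dataset$norm))
  if (length(absent)) {
    stop("marker gene(s) missing from dataset: ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  expr <- as.matrix(Matrix::t(dataset$norm[genes, , drop = FALSE]))  # bins x genes
  section <- dataset$bins$section_id
  z <- matrix(0, nrow(expr), ncol(expr), dimnames = dimnames(expr))
  for (s in unique(section)) {
    idx <- which(section == s)
    if (length(idx) < 2) {
      stop("section '", s, "' has fewer than 2 bins; z-scaling undefined",
           call. = FALSE)
    }
    sub <- expr[idx, , drop = FALSE]
    mu <- colMeans(sub)
    sdv <- apply(sub, 2, stats::sd)
    zc <- sweep(sub, 2, mu, `-`)
    zc <- sweep(zc, 2, ifelse(sdv > 0, sdv, Inf), `/`)  # zero-variance -> 0
    z[idx, ] <- zc
  }
  scores <- vapply(panel, function(g) rowMeans(z[, g, drop = FALSE]),
                   numeric(nrow(z)))
  if (nrow(z) == 1L) scores <- matrix(scores, nrow = 1, dimnames = list(NULL, names(panel)))
  tibble::as_tibble(scores) |>
    dplyr::mutate(barcode = dataset$bins$barcode, section_id = section,
                  .before = 1)
}

#' Assign a layer label to each bin from marker scores
#'
#' A bin takes the label with the highest score when that maximum is
#' strictly positive and unique; ties at the maximum or no positive score
#' give `"unassigned"`.
#'
#' @param dataset A normalized `skin_dataset`.
#' @param panel A [marker_panel()].
#' @return The dataset with a `layer_label` column added to the bin table;
#'   the score table is attached as attribute `"marker_scores"`.
#' @export
assign_layers <- function(dataset, panel = marker_panel()) {
  sc <- marker_scores(dataset, panel)
  labels <- setdiff(names(sc), c("barcode", "section_id"))
  m <- as.matrix(sc[, labels, drop = FALSE])
  lab <- apply(m, 1, function(v) {
    mx <- max(v)
    if (mx <= 0 || sum(v == mx) > 1L) "unassigned" else labels[which.max(v)]
  })
  dataset$bins$layer_label <- unname(lab)
  attr(dataset, "marker_scores") <- sc
  dataset
}

#' Layer composition per condition
#'
#' Proportion of bins assigned to each layer label within each condition;
#' proportions sum to 1 per condition.
#'
#' @param x A `skin_dataset` with labels assigned, or its bin table.
#' @return Tibble: condition, layer_label, n_bins, proportion.
#' @export
layer_composition <- function(x) {
  bins <- if (inherits(x, "skin_dataset")) x$bins else tibble::as_tibble(x)
  if (!"layer_label" %in% names(bins)) {
    stop("no layer_label column: run assign_layers() first", call. = FALSE)
  }
  if (!nrow(bins)) stop("no bins to summarize", call. = FALSE)
  bins |>
    dplyr::count(.data$condition, .data$layer_label, name = "n_bins") |>
    dplyr::group_by(.data$condition) |>
    dplyr::mutate(proportion = .data$n_bins / sum(.data$n_bins)) |>
    dplyr::ungroup()
}

#' Stacked-bar plot of layer composition across conditions
#' @param composition Output of [layer_composition()].
#' @return A ggplot object.
#' @export
plot_layer_composition <- function(composition) {
  ggplot2::ggplot(composition,
                  ggplot2::aes(x = .data$condition, y = .data$proportion,
                               fill = .data$layer_label)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::labs(x = NULL, y = "proportion of bins", fill = "layer") +
    ggplot2::theme_minimal()
}
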