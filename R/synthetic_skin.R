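#' Simulation configuration for synthetic layered skin datasets
#'
#' Defines the generative model for a Visium-HD-style binned skin dataset:
#' a square bin grid whose rows are split into horizontal bands (non-tissue
#' background on top, then granular (GC), spinous (SC) and basal (BC)
#' epidermis, with fibroblast-rich dermis (FB) below), three experimental
#' conditions (un-irradiated negative control, UV-irradiated control, and
#' UV-irradiated with treatment) with a fixed number of technical-replicate
#' sections each, and negative-binomial counts whose means combine a
#' layer-specific per-gene baseline, a condition fold on the senescence
#' panel, a per-bin log-normal depth factor and a per-section depth scalar.
#'
#' The gene panel always contains the six canonical layer markers (TP63;
#' KRT10, KRTDAP; FLG; COL1A1, TIMP1), the ten senescence/DNA-damage genes
#' (CDKN1A, CRYAB, DST, EZR, FTL, HMOX1, KRT6A, S100A2, S100A16, ZFP36),
#' thirteen mitochondrially encoded "MT-" genes, and `n_filler_genes`
#' unstructured filler genes.
#'
#' @param grid_rows,grid_cols Bin grid dimensions per section.
#' @param bin_edge_um Bin edge length in micrometres (default 16).
#' @param conditions Ordered condition labels.
#' @param sections_per_condition Technical-replicate sections per condition.
#' @param layer_geometry Named fractions of grid rows per band, in top-to-
#'   bottom order `background, GC, SC, BC, FB`; must sum to 1.
#' @param dispersion Negative-binomial size parameter (theta), > 0.
#' @param libsize_sigma Log-normal sigma of the per-bin depth factor
#'   (mean-one parameterization), >= 0.
#' @param section_depth_factor Multiplicative depth per section (recycled to
#'   `sections_per_condition`), all > 0.
#' @param uv_fold Fold induction of the senescence panel in the UV control
#'   condition (default 4).
#' @param icon_fold Fold induction under treatment; must satisfy
#'   `1 <= icon_fold <= uv_fold` (default 1.5).
#' @param mt_fraction Baseline expected fraction of a bin's counts coming
#'   from MT- genes.
#' @param mt_spike_fraction Fraction of bins whose MT- means are multiplied
#'   by `mt_spike_factor`, giving high-percent.mt bins for QC to remove.
#' @param mt_spike_factor Fold applied to MT- means in spiked bins.
#' @param n_filler_genes Number of unstructured filler genes.
#' @param marker_mean,off_layer_mean NB mean of a layer marker inside /
#'   outside its own layer.
#' @param senescence_baseline Named baseline NB means for the ten senescence
#'   genes (per bin, at depth factor 1, before condition folds).
#' @param background_mean Ambient per-gene NB mean in non-tissue bins.
#' @param seed Integer RNG seed; the whole dataset is a deterministic
#'   function of the config including this seed.
#'
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(grid_rows = 64L, grid_cols = 64L, bin_edge_um = 16,
                       conditions = c("neg_ctrl", "ctrl", "icon"),
                       sections_per_condition = 2L,
                       layer_geometry = c(background = 0.20, GC = 0.08,
                                          SC = 0.16, BC = 0.16, FB = 0.40),
                       dispersion = 2, libsize_sigma = 0.3,
                       section_depth_factor = c(1.0, 0.85),
                       uv_fold = 4.0, icon_fold = 1.5,
                       mt_fraction = 0.05, mt_spike_fraction = 0.10,
                       mt_spike_factor = 6,
                       n_filler_genes = 171L,
                       marker_mean = 10, off_layer_mean = 0.05,
                       senescence_baseline = c(
                         CDKN1A = 0.2, CRYAB = 0.5, DST = 0.15, EZR = 0.4,
                         FTL = 1.0, HMOX1 = 0.3, KRT6A = 0.1, S100A2 = 0.6,
                         S100A16 = 0.35, ZFP36 = 0.25),
                       background_mean = 0.01,
                       seed = 1L) {
  cfg <- list(
    grid_rows = as.integer(grid_rows), grid_cols = as.integer(grid_cols),
    bin_edge_um = bin_edge_um, conditions = conditions,
    sections_per_condition = as.integer(sections_per_condition),
    layer_geometry = layer_geometry, dispersion = dispersion,
    libsize_sigma = libsize_sigma,
    section_depth_factor = rep_len(section_depth_factor, sections_per_condition),
    uv_fold = uv_fold, icon_fold = icon_fold,
    mt_fraction = mt_fraction, mt_spike_fraction = mt_spike_fraction,
    mt_spike_factor = mt_spike_factor,
    n_filler_genes = as.integer(n_filler_genes),
    marker_mean = marker_mean, off_layer_mean = off_layer_mean,
    senescence_baseline = senescence_baseline,
    background_mean = background_mean,
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  bands <- c("background", "GC", "SC", "BC", "FB")
  if (!identical(names(cfg$layer_geometry), bands)) {
    stop("layer_geometry must be named fractions for background, GC, SC, BC, FB (in order)",
         call. = FALSE)
  }
  if (abs(sum(cfg$layer_geometry) - 1) > 1e-8) {
    stop("layer_geometry band fractions must sum to 1", call. = FALSE)
  }
  if (any(cfg$layer_geometry < 0)) stop("band fractions must be non-negative", call. = FALSE)
  if (!is.finite(cfg$dispersion) || cfg$dispersion <= 0) {
    stop("dispersion (NB size) must be strictly positive", call. = FALSE)
  }
  if (cfg$libsize_sigma < 0) stop("libsize_sigma must be >= 0", call. = FALSE)
  if (any(cfg$section_depth_factor <= 0)) {
    stop("section depth factors must be > 0", call. = FALSE)
  }
  if (!(cfg$icon_fold >= 1 && cfg$icon_fold <= cfg$uv_fold)) {
    stop("need 1 <= icon_fold <= uv_fold", call. = FALSE)
  }
  if (any(cfg$senescence_baseline <= 0) || cfg$marker_mean <= 0) {
    stop("expressed-gene means must be strictly positive", call. = FALSE)
  }
  invisible(cfg)
}

mt_gene_names <- function() {
  c("MT-ND1", "MT-ND2", "MT-ND3", "MT-ND4", "MT-ND4L", "MT-ND5", "MT-ND6",
    "MT-CO1", "MT-CO2", "MT-CO3", "MT-CYB", "MT-ATP6", "MT-ATP8")
}

marker_layer_map <- function() {
  c(TP63 = "BC", KRT10 = "SC", KRTDAP = "SC", FLG = "GC",
    COL1A1 = "FB", TIMP1 = "FB")
}

#' Gene panel and layer-specific baseline means implied by a config
#'
#' Builds the full simulated gene panel and its baseline NB mean for each
#' tissue layer (columns GC, SC, BC, FB plus background). Markers take
#' `marker_mean` in their own layer and `off_layer_mean` elsewhere;
#' senescence genes take their named baseline in all tissue layers; filler
#' means follow a fixed log-spaced ladder (0.05 to 2) so they are
#' reproducible without consuming RNG state; MT- gene means are set so the
#' expected MT fraction of a tissue bin's counts is `mt_fraction`.
#'
#' @param config A [sim_config()].
#' @return A list with `genes` (tibble: gene, class) and `baseline`
#'   (genes x layers numeric matrix).
#' @export
sim_gene_panel <- function(config) {
  markers <- names(marker_layer_map())
  sen <- names(config$senescence_baseline)
  mt <- mt_gene_names()
  filler <- sprintf("FILLER%03d", seq_len(config$n_filler_genes))
  genes <- c(markers, sen, mt, filler)
  layers <- c("GC", "SC", "BC", "FB", "background")
  base <- matrix(0, length(genes), length(layers),
                 dimnames = list(genes, layers))
  for (m in markers) {
    base[m, c("GC", "SC", "BC", "FB")] <- config$off_layer_mean
    base[m, marker_layer_map()[[m]]] <- config$marker_mean
  }
  base[sen, c("GC", "SC", "BC", "FB")] <- config$senescence_baseline
  if (length(filler)) {
    fm <- exp(seq(log(0.05), log(2), length.out = length(filler)))
    base[filler, c("GC", "SC", "BC", "FB")] <- fm
  }
  # MT means: expected tissue fraction mt_fraction of total counts per layer
  non_mt_total <- colSums(base[c(markers, sen, filler), c("GC", "SC", "BC", "FB"), drop = FALSE])
  mt_total <- non_mt_total * config$mt_fraction / (1 - config$mt_fraction)
  base[mt, c("GC", "SC", "BC", "FB")] <-
    matrix(rep(mt_total / length(mt), each = length(mt)), nrow = length(mt))
  base[, "background"] <- config$background_mean
  cls <- c(rep("marker", length(markers)), rep("senescence", length(sen)),
           rep("mitochondrial", length(mt)), rep("filler", length(filler)))
  list(genes = tibble::tibble(gene = genes, class = cls), baseline = base)
}

condition_fold <- function(config, condition) {
  switch(condition,
         neg_ctrl = 1.0,
         ctrl = config$uv_fold,
         icon = config$icon_fold,
         1.0)
}

layer_of_rows <- function(config) {
  # top-to-bottom horizontal bands; largest-remainder-free simple cut
  edges <- round(cumsum(config$layer_geometry) * config$grid_rows)
  edges[length(edges)] <- config$grid_rows
  bands <- names(config$layer_geometry)
  lab <- character(config$grid_rows)
  start <- 1L
  for (i in seq_along(bands)) {
    if (edges[i] >= start) lab[start:edges[i]] <- bands[i]
    start <- edges[i] + 1L
  }
  lab
}

simulate_section_counts <- function(config, panel, condition, section_idx,
                                    section_tag) {
  rows <- config$grid_rows
  cols <- config$grid_cols
  n_bins <- rows * cols
  row_layer <- layer_of_rows(config)
  array_row <- rep(seq_len(rows) - 1L, each = cols)
  array_col <- rep(seq_len(cols) - 1L, times = rows)
  layer <- row_layer[array_row + 1L]
  in_tissue <- as.integer(layer != "background")
  barcode <- sprintf("%s-%05d", section_tag, seq_len(n_bins))

  depth <- if (config$libsize_sigma > 0) {
    stats::rlnorm(n_bins, meanlog = -config$libsize_sigma^2 / 2,
                  sdlog = config$libsize_sigma)
  } else rep(1, n_bins)
  spike <- stats::runif(n_bins) < config$mt_spike_fraction
  sec_depth <- config$section_depth_factor[section_idx]
  fold <- condition_fold(config, condition)

  base <- panel$baseline[, layer, drop = FALSE]  # genes x bins
  sen <- panel$genes$gene[panel$genes$class == "senescence"]
  mt <- panel$genes$gene[panel$genes$class == "mitochondrial"]
  mu <- base
  mu[sen, in_tissue == 1L] <- mu[sen, in_tissue == 1L] * fold
  if (any(spike)) mu[mt, spike] <- mu[mt, spike] * config$mt_spike_factor
  mu <- sweep(mu, 2, depth * sec_depth, `*`)

  cnt <- matrix(stats::rnbinom(length(mu), size = config$dispersion, mu = mu),
                nrow = nrow(mu),
                dimnames = list(panel$genes$gene, barcode))
  counts <- as_sparse_counts(cnt)

  bins <- tibble::tibble(
    barcode = barcode, in_tissue = in_tissue,
    array_row = array_row, array_col = array_col,
    pxl_row = array_row * config$bin_edge_um,
    pxl_col = array_col * config$bin_edge_um,
    section_id = section_tag, condition = condition
  )
  truth <- tibble::tibble(barcode = barcode, section_id = section_tag,
                          condition = condition, true_layer = layer,
                          mt_spiked = spike)
  list(counts = counts, bins = bins, truth = truth)
}

#' Generate a seeded synthetic skin dataset, one section at a time
#'
#' Draws every condition x section dataset defined by the config from a
#' single RNG stream seeded at `config$seed`, so the full output is a
#' deterministic function of the config.
#'
#' @param config A [sim_config()].
#' @return A list of class `skin_sim` with elements:
#'   * `sections`: named list (e.g. `ctrl_s1`) of `skin_dataset` objects,
#'     one per condition x section;
#'   * `truth`: ground truth — `bin_layers` (tibble: barcode, section,
#'     condition, true layer, MT-spike flag), `gene_means` (long tibble of
#'     true expected means per gene x layer x condition at depth 1),
#'     `senescence_genes`, and the per-condition fold table;
#'   * `config`: the config used.
#' @export
generate_dataset <- function(config) {
  validate_sim_config(config)
  panel <- sim_gene_panel(config)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed)

  sections <- list()
  truths <- list()
  for (cond in config$conditions) {
    for (s in seq_len(config$sections_per_condition)) {
      tag <- sprintf("%s_s%d", cond, s)
      sec <- simulate_section_counts(config, panel, cond, s, tag)
      sections[[tag]] <- skin_dataset(sec$counts, sec$bins,
                                      bin_edge_um = config$bin_edge_um)
      truths[[tag]] <- sec$truth
    }
  }
  folds <- tibble::tibble(
    condition = config$conditions,
    senescence_fold = vapply(config$conditions, condition_fold,
                             numeric(1), config = config)
  )
  layers <- c("GC", "SC", "BC", "FB")
  gm <- tidyr::expand_grid(gene = panel$genes$gene, condition = config$conditions) |>
    dplyr::left_join(panel$genes, by = "gene")
  base_long <- tibble::as_tibble(panel$baseline[, layers], rownames = "gene") |>
    tidyr::pivot_longer(-"gene", names_to = "layer", values_to = "baseline_mean")
  gm <- gm |>
    dplyr::left_join(base_long, by = "gene", relationship = "many-to-many") |>
    dplyr::left_join(folds, by = "condition") |>
    dplyr::mutate(true_mean = .data$baseline_mean *
                    ifelse(.data$class == "senescence", .data$senescence_fold, 1)) |>
    dplyr::select("gene", "class", "condition", "layer", "baseline_mean", "true_mean")

  structure(list(
    sections = sections,
    truth = list(bin_layers = dplyr::bind_rows(truths),
                 gene_means = gm,
                 senescence_genes = names(config$senescence_baseline),
                 condition_folds = folds),
    config = config
  ), class = "skin_sim")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' @export
print.skin_sim <- function(x, ...) {
  cat(sprintf("<skin_sim> %d sections (%s x %d), %d genes, seed %d\n",
              length(x$sections), paste(x$config$conditions, collapse = "/"),
              x$config$sections_per_condition,
              nrow(x$sections[[1]]$counts), x$config$seed))
  invisible(x)
}

#' Write one simulated section to the standard 10x-style binned layout
#'
#' Emits `matrix.mtx` (Matrix Market coordinate counts), `features.tsv`
#' (gene_id, gene_name; no header), `barcodes.tsv` (no header),
#' `tissue_positions.csv` (with header) and `scalefactors.json`
#' (bin edge length plus section/condition metadata) — the file set
#' [read_dataset()] consumes.
#'
#' @param dataset A `skin_dataset` (a single section).
#' @param directory Output directory; created if needed.
#' @return Invisibly, the directory path.
#' @export
write_dataset <- function(dataset, directory) {
  stopifnot(inherits(dataset, "skin_dataset"))
  ok <- dir.exists(directory) || dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  if (!ok) stop("cannot create directory: ", directory, call. = FALSE)
  Matrix::writeMM(dataset$counts, file.path(directory, "matrix.mtx"))
  readr::write_tsv(
    tibble::tibble(gene_id = rownames(dataset$counts),
                   gene_name = rownames(dataset$counts)),
    file.path(directory, "features.tsv"), col_names = FALSE)
  readr::write_tsv(tibble::tibble(barcode = colnames(dataset$counts)),
                   file.path(directory, "barcodes.tsv"), col_names = FALSE)
  readr::write_csv(
    dataset$bins[, c("barcode", "in_tissue", "array_row", "array_col",
                     "pxl_row", "pxl_col")],
    file.path(directory, "tissue_positions.csv"))
  meta <- list(bin_edge_um = dataset$bin_edge_um,
               section_id = unique(dataset$bins$section_id),
               condition = unique(dataset$bins$condition))
  jsonlite::write_json(meta, file.path(directory, "scalefactors.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(directory)
}

#' Write every section of a simulation under one root directory
#'
#' @param sim A `skin_sim` from [generate_dataset()].
#' @param root Root output directory; one subdirectory per section.
#' @return Invisibly, the vector of section directories.
#' @export
write_sim <- function(sim, root) {
  dirs <- vapply(names(sim$sections), function(tag) {
    write_dataset(sim$sections[[tag]], file.path(root, tag))
    file.path(root, tag)
  }, character(1))
  invisible(dirs)
}
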