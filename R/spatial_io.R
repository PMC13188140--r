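#' Read a binned spatial expression dataset from the 10x-style file layout
#'
#' Expects the five-file layout written by [write_dataset()]: Matrix Market
#' counts (`matrix.mtx`), `features.tsv` and `barcodes.tsv` without headers,
#' `tissue_positions.csv` with a header, and `scalefactors.json` carrying the
#' bin edge length (and, when present, section/condition labels). QC columns
#' (`n_count`, `n_feature`, `percent_mt`) are left unpopulated; they are
#' computed by [compute_qc_metrics()].
#'
#' @param directory Directory holding the five files.
#' @return A [skin_dataset()].
#' @export
read_dataset <- function(directory) {
  paths <- file.path(directory, c("matrix.mtx", "features.tsv", "barcodes.tsv",
                                  "tissue_positions.csv", "scalefactors.json"))
  missing <- paths[!file.exists(paths)]
  if (length(missing)) {
    stop("missing dataset file(s): ", paste(basename(missing), collapse = ", "),
         call. = FALSE)
  }
  m <- Matrix::readMM(paths[1])
  feats <- readr::read_tsv(paths[2], col_names = c("gene_id", "gene_name"),
                           col_types = "cc", progress = FALSE)
  bcs <- readr::read_tsv(paths[3], col_names = "barcode", col_types = "c",
                         progress = FALSE)
  pos <- readr::read_csv(paths[4], col_types = readr::cols(
    barcode = readr::col_character(), in_tissue = readr::col_integer(),
    array_row = readr::col_integer(), array_col = readr::col_integer(),
    pxl_row = readr::col_double(), pxl_col = readr::col_double()),
    progress = FALSE)
  meta <- jsonlite::read_json(paths[5], simplifyVector = TRUE)

  if (nrow(m) != nrow(feats)) {
    stop(sprintf("dimension mismatch: matrix has %d rows but features.tsv lists %d genes",
                 nrow(m), nrow(feats)), call. = FALSE)
  }
  if (ncol(m) != nrow(bcs)) {
    stop(sprintf("dimension mismatch: matrix has %d columns but barcodes.tsv lists %d barcodes",
                 ncol(m), nrow(bcs)), call. = FALSE)
  }
  if (nrow(pos) != nrow(bcs)) {
    stop("dimension mismatch: tissue_positions.csv and barcodes.tsv disagree",
         call. = FALSE)
  }
  if (anyDuplicated(bcs$barcode)) stop("duplicate barcodes", call. = FALSE)
  m <- Matrix::drop0(as_sparse_counts(m))
  if (length(m@x) && min(m@x) < 0) stop("negative counts", call. = FALSE)
  dimnames(m) <- list(feats$gene_name, bcs$barcode)

  bins <- dplyr::left_join(bcs, pos, by = "barcode")
  bins$section_id <- if (!is.null(meta$section_id)) meta$section_id else "s1"
  bins$condition <- if (!is.null(meta$condition)) meta$condition else NA_character_
  edge <- if (!is.null(meta$bin_edge_um)) meta$bin_edge_um else 16
  skin_dataset(m, bins, bin_edge_um = edge)
}

#' Pool tissue sections into one dataset
#'
#' Column-wise concatenation of sections over an identical gene panel.
#' Barcodes are suffixed with their section id so they stay unique, and the
#' section/condition columns are carried along, which is what lets
#' condition-level metrics pool spatial bins across the sections of a
#' condition.
#'
#' @param datasets A list of `skin_dataset` objects (or a `skin_sim`, whose
#'   sections are taken).
#' @return A single merged [skin_dataset()].
#' @export
merge_sections <- function(datasets) {
  if (inherits(datasets, "skin_sim")) datasets <- datasets$sections
  if (inherits(datasets, "skin_dataset")) datasets <- list(datasets)
  stopifnot(length(datasets) >= 1)
  panels <- lapply(datasets, function(d) rownames(d$counts))
  if (!all(vapply(panels, identical, logical(1), y = panels[[1]]))) {
    stop("gene panels differ across sections; cannot merge", call. = FALSE)
  }
  edges <- unique(vapply(datasets, function(d) d$bin_edge_um, numeric(1)))
  if (length(edges) != 1) stop("bin_edge_um differs across sections", call. = FALSE)

  pieces <- lapply(datasets, function(d) {
    tag <- unique(d$bins$section_id)
    suffix <- if (length(tag) == 1 && !startsWith(d$bins$barcode[1] %||% "", tag)) {
      paste0(d$bins$barcode, "-", tag)
    } else d$bins$barcode
    m <- d$counts
    colnames(m) <- suffix
    b <- d$bins
    b$barcode <- suffix
    list(m = m, b = b)
  })
  merged <- do.call(cbind, lapply(pieces, `[[`, "m"))
  bins <- dplyr::bind_rows(lapply(pieces, `[[`, "b"))
  skin_dataset(merged, bins, bin_edge_um = edges)
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0) b else a
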