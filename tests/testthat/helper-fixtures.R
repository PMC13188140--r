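# Small configs and hand-built datasets shared across test files.

# quick config: small grid, single section per condition, keeps tests fast
quick_config <- function(seed = 1, ...) {
  sim_config(grid_rows = 24L, grid_cols = 24L, sections_per_condition = 1L,
             section_depth_factor = 1, n_filler_genes = 20L, seed = seed, ...)
}

# tiny hand-built dataset: explicit counts, one section
toy_dataset <- function(counts, in_tissue = rep(1L, ncol(counts)),
                        condition = "ctrl", section_id = "s1",
                        bin_edge_um = 16) {
  n <- ncol(counts)
  stopifnot(!is.null(rownames(counts)))
  if (is.null(colnames(counts))) colnames(counts) <- sprintf("bin%03d", seq_len(n))
  bins <- tibble::tibble(
    barcode = colnames(counts), in_tissue = as.integer(in_tissue),
    array_row = seq_len(n) - 1L, array_col = 0L,
    pxl_row = (seq_len(n) - 1L) * bin_edge_um, pxl_col = 0,
    section_id = section_id, condition = condition
  )
  skin_dataset(counts, bins, bin_edge_um = bin_edge_um)
}

# random sparse count matrix with gene names (no MT- genes unless asked)
random_counts <- function(n_genes, n_bins, lambda = 0.5, mt_genes = 0) {
  m <- matrix(stats::rpois(n_genes * n_bins, lambda), n_genes, n_bins)
  rn <- sprintf("G%03d", seq_len(n_genes))
  if (mt_genes > 0) rn[seq_len(mt_genes)] <- sprintf("MT-X%d", seq_len(mt_genes))
  dimnames(m) <- list(rn, sprintf("b%04d", seq_len(n_bins)))
  m
}

# independent oracle: two-sided rank-sum p by full enumeration of
# rank assignments (tie-free samples only)
enumerate_rank_sum_p <- function(x, y) {
  n1 <- length(x)
  pooled <- c(x, y)
  stopifnot(!anyDuplicated(pooled))
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(n1)])
  all_w <- apply(utils::combn(length(pooled), n1), 2, function(idx) sum(r[idx]))
  mu <- n1 * (length(pooled) + 1) / 2
  mean(abs(all_w - mu) >= abs(w_obs - mu) - 1e-12)
}
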