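test_that("config invariants are enforced", {
  expect_error(sim_config(icon_fold = 5, uv_fold = 4), "icon_fold")
  expect_error(sim_config(icon_fold = 0.5), "icon_fold")
  expect_error(sim_config(layer_geometry = c(background = 0.5, GC = 0.1,
                                             SC = 0.1, BC = 0.1, FB = 0.1)),
               "sum to 1")
  expect_error(sim_config(dispersion = 0), "dispersion")
  expect_error(sim_config(libsize_sigma = -1), "libsize_sigma")
})

test_that("identical seed and config give byte-identical datasets", {
  cfg <- quick_config(seed = 7)
  a <- generate_dataset(cfg)
  b <- generate_dataset(cfg)
  for (tag in names(a$sections)) {
    expect_identical(a$sections[[tag]]$counts, b$sections[[tag]]$counts)
    expect_identical(a$sections[[tag]]$bins, b$sections[[tag]]$bins)
  }
  expect_identical(a$truth, b$truth)
  d <- generate_dataset(quick_config(seed = 8))
  expect_false(identical(a$sections[[1]]$counts, d$sections[[1]]$counts))
})

test_that("gene panel contains markers, senescence, MT and filler genes", {
  panel <- sim_gene_panel(quick_config())
  expect_true(all(c("TP63", "KRT10", "KRTDAP", "FLG", "COL1A1", "TIMP1")
                  %in% panel$genes$gene))
  expect_true(all(senescence_panel() %in% panel$genes$gene))
  expect_gte(sum(startsWith(panel$genes$gene, "MT-")), 5)
  expect_gte(sum(panel$genes$class == "filler"), 5)
})

test_that("empirical ctrl mean of CDKN1A matches the analytic NB mean", {
  # baseline 0.2/bin, uv_fold 4 => mean 0.8; 64x64 all-tissue grid, no
  # depth heterogeneity, so the sample mean obeys the law of large numbers
  cfg <- sim_config(grid_rows = 64L, grid_cols = 64L,
                    sections_per_condition = 1L, section_depth_factor = 1,
                    libsize_sigma = 0, conditions = "ctrl",
                    layer_geometry = c(background = 0, GC = 0.1, SC = 0.2,
                                       BC = 0.2, FB = 0.5),
                    n_filler_genes = 5L, seed = 3)
  sim <- generate_dataset(cfg)
  counts <- sim$sections[[1]]$counts
  expect_equal(ncol(counts), 4096L)
  emp <- mean(counts["CDKN1A", ])
  expect_lt(abs(emp - 0.8) / 0.8, 0.10)
})

test_that("null generator makes senescence means indistinguishable across conditions", {
  # uv_fold = icon_fold = 1: rank-sum on raw CDKN1A counts between ctrl and
  # neg_ctrl should be non-significant in at least 9 of 10 seeds
  pass <- vapply(1:10, function(s) {
    cfg <- sim_config(grid_rows = 46L, grid_cols = 46L, uv_fold = 1,
                      icon_fold = 1, sections_per_condition = 1L,
                      section_depth_factor = 1,
                      conditions = c("neg_ctrl", "ctrl"),
                      n_filler_genes = 5L, seed = s)
    sim <- generate_dataset(cfg)
    g <- function(tag) {
      d <- sim$sections[[tag]]
      as.numeric(d$counts["CDKN1A", d$bins$in_tissue == 1])
    }
    rank_sum_test(g("ctrl_s1"), g("neg_ctrl_s1"))$p_value > 0.01
  }, logical(1))
  expect_gte(sum(pass), 9)
})

test_that("true effect ordering is monotone when uv_fold >= icon_fold >= 1", {
  sim <- generate_dataset(quick_config())
  gm <- sim$truth$gene_means
  sen <- dplyr::filter(gm, .data$class == "senescence")
  wide <- tidyr::pivot_wider(sen, names_from = "condition",
                             values_from = "true_mean",
                             id_cols = c("gene", "layer"))
  expect_true(all(wide$ctrl >= wide$icon & wide$icon >= wide$neg_ctrl))
})

test_that("MT-spiked bins have higher expected percent.mt than unspiked bins", {
  sim <- generate_dataset(sim_config(grid_rows = 48L, grid_cols = 48L,
                                     sections_per_condition = 1L,
                                     conditions = "ctrl", seed = 2))
  d <- compute_qc_metrics(sim$sections[[1]])
  truth <- sim$truth$bin_layers
  tissue <- d$bins$in_tissue == 1
  spiked <- truth$mt_spiked[match(d$bins$barcode, truth$barcode)]
  expect_gt(mean(d$bins$percent_mt[tissue & spiked]),
            mean(d$bins$percent_mt[tissue & !spiked]))
})

test_that("NB marginal moments are recovered at large n", {
  # FTL in neg_ctrl, no depth noise: NB(mu = 1, theta = 2),
  # var = mu + mu^2/theta = 1.5
  cfg <- sim_config(grid_rows = 64L, grid_cols = 64L, libsize_sigma = 0,
                    sections_per_condition = 1L, section_depth_factor = 1,
                    conditions = "neg_ctrl",
                    layer_geometry = c(background = 0, GC = 0.1, SC = 0.2,
                                       BC = 0.2, FB = 0.5),
                    n_filler_genes = 5L, seed = 11)
  x <- as.numeric(generate_dataset(cfg)$sections[[1]]$counts["FTL", ])
  expect_lt(abs(mean(x) - 1) / 1, 0.1)
  expect_lt(abs(stats::var(x) - 1.5) / 1.5, 0.15)
})

test_that("ground truth covers every generated bin exactly once", {
  sim <- generate_dataset(quick_config())
  all_bins <- unlist(lapply(sim$sections, function(d) d$bins$barcode))
  expect_setequal(sim$truth$bin_layers$barcode, all_bins)
  expect_equal(anyDuplicated(sim$truth$bin_layers$barcode), 0L)
})

test_that("write_dataset emits the five-file layout and round-trips", {
  sim <- generate_dataset(quick_config())
  dir <- withr::local_tempdir()
  write_dataset(sim$sections[[1]], dir)
  expect_setequal(list.files(dir),
                  c("matrix.mtx", "features.tsv", "barcodes.tsv",
                    "tissue_positions.csv", "scalefactors.json"))
  back <- read_dataset(dir)
  expect_equal(as.matrix(back$counts), as.matrix(sim$sections[[1]]$counts))
  expect_equal(back$bins$array_row, sim$sections[[1]]$bins$array_row)
  expect_equal(back$bins$in_tissue, sim$sections[[1]]$bins$in_tissue)
  expect_equal(back$bin_edge_um, 16)
})

test_that("an empty dataset writes valid files with zero data rows", {
  m <- Matrix::Matrix(0, nrow = 3, ncol = 0, sparse = TRUE,
                      dimnames = list(c("A", "B", "C"), character(0)))
  empty <- skin_dataset(m, tibble::tibble(
    barcode = character(0), in_tissue = integer(0), array_row = integer(0),
    array_col = integer(0), pxl_row = numeric(0), pxl_col = numeric(0),
    section_id = character(0), condition = character(0)))
  dir <- withr::local_tempdir()
  write_dataset(empty, dir)
  back <- read_dataset(dir)
  expect_equal(dim(back$counts), c(3L, 0L))
  expect_equal(nrow(back$bins), 0L)
})

test_that("3 conditions x 2 sections yield 6 dataset directories with distinct metadata", {
  cfg <- sim_config(grid_rows = 8L, grid_cols = 8L, seed = 1)
  sim <- generate_dataset(cfg)
  root <- withr::local_tempdir()
  dirs <- write_sim(sim, root)
  expect_length(dirs, 6L)
  meta <- lapply(dirs, function(d)
    jsonlite::read_json(file.path(d, "scalefactors.json"), simplifyVector = TRUE))
  pairs <- vapply(meta, function(m) paste(m$condition, m$section_id), character(1))
  expect_equal(anyDuplicated(pairs), 0L)
})
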