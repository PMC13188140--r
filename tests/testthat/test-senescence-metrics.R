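test_that("positive-bin counting matches toy vectors and the raw-nonzero oracle", {
  m <- matrix(c(0L, 1L, 0L, 3L, 2L,
                0L, 0L, 0L, 0L, 0L,
                1L, 1L, 1L, 1L, 1L), nrow = 3, byrow = TRUE,
              dimnames = list(c("GA", "GB", "KEEP"), sprintf("b%d", 1:5)))
  d <- normalize_counts(toy_dataset(m))
  expect_equal(positive_bins(d, "GA"), 3L)
  expect_equal(positive_bins(d, "GB"), 0L)
  expect_error(positive_bins(d, "NOPE"), "unknown gene")

  set.seed(99)
  for (i in 1:100) {
    m <- random_counts(12, 30, lambda = 0.3)
    m["G001", ] <- pmax(m["G001", ], 1L)   # keep totals positive
    d <- normalize_counts(toy_dataset(m))
    g <- sample(rownames(m), 1)
    expect_equal(positive_bins(d, g), sum(m[g, ] > 0))
  }
})

test_that("tissue area follows the printed bin-area constant", {
  expect_identical(tissue_area(1, 16), 0.000256)
  expect_equal(tissue_area(0), 0)
  expect_equal(tissue_area(4069), 1.041664)
  expect_error(tissue_area(-1), "negative")
  expect_error(tissue_area(1, 0), "positive")
})

test_that("density arithmetic and bounds", {
  expect_equal(positive_density(256, tissue_area(1000)), 1000)
  expect_equal(positive_density(0, 0.5), 0)
  # all bins positive: density = 1 / bin area
  expect_equal(positive_density(1000, tissue_area(1000)), 3906.25)
  expect_error(positive_density(5, 0), "positive")
})

test_that("condition pooling sums counts and areas before dividing", {
  st <- tibble::tibble(
    gene = "G", condition = "ctrl", section_id = c("s1", "s2"),
    n_positive_bins = c(10L, 30L), n_tissue_bins = c(391L, 1172L),
    tissue_area_mm2 = c(0.1, 0.3),
    density_per_mm2 = c(100, 100))
  expect_equal(pool_by_condition(st)$density_per_mm2, 100)

  st2 <- st
  st2$n_positive_bins <- c(10L, 10L)
  st2$density_per_mm2 <- c(100, 100 / 3)
  pooled <- pool_by_condition(st2)
  expect_equal(pooled$density_per_mm2, 50)          # bins-pooled estimator
  expect_false(isTRUE(all.equal(pooled$density_per_mm2,
                                mean(st2$density_per_mm2))))  # != 66.7
  expect_equal(pooled$n_positive_bins, sum(st2$n_positive_bins))
})

test_that("single-section pooling is the identity", {
  sim <- generate_dataset(quick_config())
  d <- merge_sections(sim) |> compute_qc_metrics() |> apply_qc() |>
    normalize_counts()
  per_sec <- density_by_section(d, c("CDKN1A", "FTL"))
  pooled <- pool_by_condition(per_sec)
  j <- dplyr::inner_join(per_sec, pooled, by = c("gene", "condition"))
  expect_equal(j$density_per_mm2.x, j$density_per_mm2.y)
})

test_that("pooled metrics are conserved when a section is split in half", {
  sim <- generate_dataset(sim_config(grid_rows = 32L, grid_cols = 32L,
                                     sections_per_condition = 1L,
                                     conditions = "ctrl", seed = 5))
  d <- merge_sections(sim) |> compute_qc_metrics() |> apply_qc() |>
    normalize_counts()
  whole <- pool_by_condition(density_by_section(d, senescence_panel()))

  half <- d
  n <- ncol(d$counts)
  half$bins$section_id <- rep(c("sA", "sB"), length.out = n)
  split <- pool_by_condition(density_by_section(half, senescence_panel()))
  expect_equal(split$n_positive_bins, whole$n_positive_bins)
  expect_equal(split$tissue_area_mm2, whole$tissue_area_mm2)
  expect_equal(split$density_per_mm2, whole$density_per_mm2)
})

test_that("densities are invariant to the normalization scale factor", {
  sim <- generate_dataset(quick_config())
  d <- merge_sections(sim) |> compute_qc_metrics() |> apply_qc()
  d1 <- density_by_condition(normalize_counts(d, 1e4))
  d2 <- density_by_condition(normalize_counts(d, 1e3))
  expect_equal(d1, d2, ignore_attr = TRUE)
})

test_that("directional consistency enumerates cross-section sign agreement", {
  mk <- function(cond, pos) tibble::tibble(
    gene = "G", condition = cond, section_id = paste0(cond, "_s", seq_along(pos)),
    n_positive_bins = as.integer(pos), n_tissue_bins = 1000L,
    tissue_area_mm2 = 0.25, density_per_mm2 = pos / 0.25)

  # both ctrl sections above both icon sections: unanimous
  st <- dplyr::bind_rows(mk("ctrl", c(75, 78)), mk("icon", c(25, 30)))
  expect_equal(directional_consistency(st, "ctrl", "icon")$consistency, 1.0)

  # hand enumeration: pairs (300,112) x (100,120) -> +200 +180 +12 -8,
  # 3 of 4 agree with the pooled (positive) difference
  st2 <- dplyr::bind_rows(mk("ctrl", c(75, 28)), mk("icon", c(25, 30)))
  cons <- directional_consistency(st2, "ctrl", "icon")
  expect_gt(cons$pooled_difference, 0)
  expect_equal(cons$n_pairs, 4L)
  expect_equal(cons$consistency, 0.75)

  # pooled difference exactly zero with nonzero pair differences:
  # (200,100) x (160,140) -> +40 +60 -60 -40, sign(0) agrees only with 0
  st3 <- dplyr::bind_rows(mk("ctrl", c(50, 25)), mk("icon", c(40, 35)))
  cons3 <- directional_consistency(st3, "ctrl", "icon")
  expect_equal(cons3$pooled_difference, 0)
  expect_equal(cons3$consistency, 0)

  expect_error(directional_consistency(st[0, ], "ctrl", "icon"), "section")
})

test_that("pooled density recovers the UV induction and treatment attenuation", {
  for (s in 1:2) {
    sim <- generate_dataset(sim_config(seed = s))
    d <- merge_sections(sim) |> compute_qc_metrics() |> apply_qc() |>
      normalize_counts()
    wide <- density_by_condition(d) |>
      dplyr::select(gene, condition, density_per_mm2) |>
      tidyr::pivot_wider(names_from = condition, values_from = density_per_mm2)
    expect_gte(sum(wide$ctrl > wide$neg_ctrl & wide$icon < wide$ctrl), 8)
  }
})
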