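test_that("population_density divides counts by scope area", {
  area <- pi * 0.6^2  # 1.13097 mm^2
  cells <- make_cells(124, seed = 3)
  cells$cd8 <- TRUE
  cells$ck <- cells$cd68 <- cells$foxp3 <- FALSE
  expect_equal(population_density(cells, "cd8", "whole", area), 124 / area)
  expect_equal(round(population_density(cells, "cd8", "whole", area), 2), 109.64)
  expect_equal(population_density(make_cells(0), "cd8", "whole", area), 0)
  # CK+PD-L1+ worked example: 7290 matching cells on the default core
  expect_equal(round(7290 / area, 1), 6445.8)
  # zero scope area with nonzero count is a hard error; zero/zero is 0
  tum <- dplyr::mutate(cells, compartment = "tumor")
  expect_error(population_density(tum, "cd8", "tumor", area,
                                  compartment_areas = list(tumor = 0, stroma = area)),
               "zero scope area")
  expect_equal(population_density(tum, "cd8", "stroma", area,
                                  compartment_areas = list(tumor = area, stroma = 0)),
               0)
})

test_that("marker_fraction matches a brute-force recount and respects the missing contract", {
  cells <- tibble::tibble(
    cell_id = as.character(1:12), core_id = "c", x_um = 1, y_um = 1,
    compartment = rep(c("tumor", "stroma"), c(10, 2)),
    ck = FALSE, cd8 = c(rep(TRUE, 10), FALSE, FALSE), cd68 = FALSE, foxp3 = FALSE,
    pd1 = c(rep(TRUE, 4), rep(FALSE, 8)), pdl1 = FALSE
  )
  expect_equal(marker_fraction(cells, "cd8", "pd1", "tumor"), 0.4)
  expect_true(is.na(marker_fraction(cells, "cd8", "pd1", "stroma")))

  for (seed in 1:50) {
    tab <- make_cells(40, seed = seed)
    for (scope in c("tumor", "stroma", "whole")) {
      keep <- if (scope == "whole") rep(TRUE, nrow(tab)) else tab$compartment == scope
      base_n <- sum(tab$cd8[keep])
      expected <- if (base_n == 0) NA_real_ else sum(tab$cd8[keep] & tab$pd1[keep]) / base_n
      expect_identical(marker_fraction(tab, "cd8", "pd1", scope), expected)
    }
  }
})

test_that("compartment_gradient follows the stated sign convention", {
  expect_equal(compartment_gradient(0.6, 0.2), 40)
  expect_equal(compartment_gradient(0.2, 0.6), -40)
  expect_equal(compartment_gradient(0.37, 0.37), 0)
  expect_true(is.na(compartment_gradient(NA, 0.5)))
})

test_that("overall_median_density uses the midpoint convention", {
  prof <- tibble::tibble(population = "cd8", scope = "whole", density = c(1, 2, 3))
  expect_equal(overall_median_density(prof, "cd8"), 2)
  expect_equal(overall_median_density(prof[1, ], "cd8"), 1)
  prof4 <- tibble::tibble(population = "cd8", scope = "whole", density = 1:4)
  expect_equal(overall_median_density(prof4, "cd8"), 2.5)
  expect_error(overall_median_density(prof, "cd99"))
})

test_that("feature matrix is complete, stable and order-invariant", {
  co <- generate_cohort(synthetic_config(n_patients = 6, rng_seed = 2))
  fm <- build_feature_matrix(co)
  expect_equal(nrow(fm), nrow(co$cores))
  expect_false(anyNA(fm))
  manifest <- attr(fm, "manifest")
  expect_equal(manifest$variable, setdiff(names(fm), "core_id"))
  expect_equal(length(manifest$variable), 17)

  # permuting cell rows leaves the matrix unchanged
  set.seed(9)
  co_perm <- co
  co_perm$cells <- co$cells[sample(nrow(co$cells)), ]
  fm_perm <- build_feature_matrix(co_perm)
  expect_equal(as.data.frame(fm), as.data.frame(fm_perm), ignore_attr = TRUE)
})

test_that("tumor and stroma counts are additive and densities scale with area", {
  co <- generate_cohort(synthetic_config(n_patients = 4, rng_seed = 8))
  prof <- core_profiles(co)
  wide <- tidyr::pivot_wider(
    dplyr::filter(prof, .data$metric == "density"),
    id_cols = c("core_id", "population"), names_from = "scope",
    values_from = "density"
  )
  areas <- co$cores
  for (i in seq_len(nrow(wide))) {
    core <- areas[areas$core_id == wide$core_id[i], ]
    cells <- co$cells[co$cells$core_id == core$core_id, ]
    p_tumor <- mean(cells$compartment == "tumor")
    # density * estimated scope area recovers the raw counts, which add up
    n_tumor <- wide$tumor[i] * p_tumor * core$area_mm2
    n_stroma <- wide$stroma[i] * (1 - p_tumor) * core$area_mm2
    n_whole <- wide$whole[i] * core$area_mm2
    expect_equal(n_tumor + n_stroma, n_whole, tolerance = 1e-8)
  }
  # linear scaling: halving the area doubles every density
  cells1 <- make_cells(30, seed = 4)
  d_full <- population_density(cells1, "cd8", "whole", 2)
  d_half <- population_density(cells1, "cd8", "whole", 1)
  expect_equal(d_half, 2 * d_full)
})

test_that("a zero-cell core yields an all-zero density row with a warning", {
  co <- make_small_cohort(n_patients = 2, cells_per_core = 8)
  co$cells <- co$cells[co$cells$core_id != "P01_c1", ]
  expect_warning(fm <- build_feature_matrix(co, include_fractions = FALSE),
                 "zero cells")
  row <- fm[fm$core_id == "P01_c1", -1]
  expect_true(all(row == 0))
})
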