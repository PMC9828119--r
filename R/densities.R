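# Per-core feature engineering: population densities (cells/mm^2), conditional
# marker fractions, tumor-stroma gradients, and the cores x variables matrix
# that feeds clustering.
#
# Compartment areas are not part of a per-cell export, so tumor/stroma areas
# are approximated by default as (compartment cell count / total cell count) *
# core area; a supplied-area override is available. The approximation keeps
# the additivity identity: tumor count + stroma count = whole count, and
# tumor area + stroma area = core area.

scope_area <- function(cells, scope, area_mm2, compartment_areas = NULL) {
  if (scope == "whole") return(area_mm2)
  if (!is.null(compartment_areas)) return(unname(compartment_areas[[scope]]))
  n_total <- nrow(cells)
  if (n_total == 0) return(0)
  sum(cells$compartment == scope) / n_total * area_mm2
}

#' Population density within a compartment scope
#'
#' Count of cells matching a population predicate inside the scope, divided by
#' the scope's area in mm^2.
#'
#' @param cells Cell tibble (one core).
#' @param population Character vector of marker columns (all must be positive)
#'   or a predicate function on the cell tibble; see [population_definitions()].
#' @param scope `"tumor"`, `"stroma"` or `"whole"`.
#' @param area_mm2 Whole-core area in mm^2.
#' @param compartment_areas Optional named list/vector with `tumor` and
#'   `stroma` areas in mm^2, overriding the cell-count-proportional
#'   approximation.
#' @return Density in cells/mm^2. Zero area with zero matching cells gives 0;
#'   zero area with a nonzero count is an error.
#' @export
population_density <- function(cells, population, scope = "whole", area_mm2,
                               compartment_areas = NULL) {
  stopifnot(scope %in% c("tumor", "stroma", "whole"), area_mm2 > 0)
  mask <- population_mask(cells, population)
  if (scope != "whole") mask <- mask & cells$compartment == scope
  n <- sum(mask)
  a <- scope_area(cells, scope, area_mm2, compartment_areas)
  if (a <= 0) {
    if (n == 0) return(0)
    rlang::abort("population_density: zero scope area with a nonzero cell count.")
  }
  n / a
}

#' Conditional marker fraction within a scope
#'
#' Fraction of base-population cells in the scope that are also positive for
#' `marker`. An empty denominator yields `NA` (never 0): absence of the base
#' population is missing information, not zero expression.
#'
#' @param cells Cell tibble.
#' @param base Base-population predicate (as in [population_density()]).
#' @param marker Marker column name.
#' @param scope `"tumor"`, `"stroma"` or `"whole"`.
#' @return Proportion in \[0, 1\], or `NA_real_`.
#' @export
marker_fraction <- function(cells, base, marker, scope = "whole") {
  stopifnot(scope %in% c("tumor", "stroma", "whole"), marker %in% names(cells))
  mask <- population_mask(cells, base)
  if (scope != "whole") mask <- mask & cells$compartment == scope
  n_base <- sum(mask)
  if (n_base == 0) return(NA_real_)
  sum(mask & cells[[marker]]) / n_base
}

#' Tumor-stroma expression gradient
#'
#' Percentage-point change of a marker fraction across compartments:
#' `100 * (fraction_tumor - fraction_stroma)`. Positive values mean higher
#' expression in the tumor compartment, negative values higher expression in
#' the stroma. Missing on either side propagates.
#'
#' @param fraction_tumor,fraction_stroma Proportions in \[0, 1\] (vectorized).
#' @return Percentage points in \[-100, 100\].
#' @export
compartment_gradient <- function(fraction_tumor, fraction_stroma) {
  100 * (fraction_tumor - fraction_stroma)
}

#' Overall median density (OMD) of a population across cores
#'
#' The median, over the cores of a cluster, of the whole-core density of a
#' population — the summary used to characterize and name immune phenotypes.
#' Even-sized sets use the midpoint (standard [stats::median()]) convention.
#'
#' @param profiles Long profile tibble from [core_profiles()] (or any tibble
#'   with `population`, `scope`, `density` columns), restricted to the cores of
#'   one cluster.
#' @param population Population name, e.g. `"cd8"` or `"ck_pdl1"`.
#' @return OMD in cells/mm^2.
#' @export
overall_median_density <- function(profiles, population) {
  rows <- profiles$population == population & profiles$scope == "whole"
  if (!any(rows)) rlang::abort("overall_median_density: no cores / unknown population.")
  median(profiles$density[rows])
}

#' Long per-core density and fraction profiles
#'
#' Densities of every canonical population in tumor, stroma and whole-core
#' scope, plus the conditional marker fractions, one row per core x metric.
#'
#' @param x A `timephen_cohort`.
#' @return A tibble with columns `core_id`, `metric` (`"density"` or
#'   `"fraction"`), `population`, `scope`, `density`, `fraction`.
#' @export
core_profiles <- function(x) {
  stopifnot(inherits(x, "timephen_cohort"))
  pops <- population_definitions()
  purrr::map(seq_len(nrow(x$cores)), function(i) {
    core <- x$cores[i, ]
    cells <- x$cells[x$cells$core_id == core$core_id, ]
    dens <- tidyr::expand_grid(population = names(pops),
                               scope = c("tumor", "stroma", "whole"))
    dens$density <- purrr::map2_dbl(dens$population, dens$scope, function(p, s) {
      population_density(cells, pops[[p]], s, core$area_mm2)
    })
    dens$metric <- "density"
    frac <- tibble(
      population = c("pd1_given_cd8", "pd1_given_cd8", "pdl1_given_cd68",
                     "pdl1_given_cd68", "pdl1_given_ck"),
      scope = c("tumor", "stroma", "tumor", "stroma", "tumor"),
      base = list("cd8", "cd8", "cd68", "cd68", "ck"),
      marker = c("pd1", "pd1", "pdl1", "pdl1", "pdl1")
    )
    frac$fraction <- purrr::pmap_dbl(frac[c("base", "marker", "scope")],
                                     function(base, marker, scope) {
                                       marker_fraction(cells, base, marker, scope)
                                     })
    frac$metric <- "fraction"
    dplyr::bind_rows(dens, dplyr::select(frac, -"base", -"marker")) |>
      dplyr::mutate(core_id = core$core_id, .before = 1)
  }) |> dplyr::bind_rows()
}

# canonical wide variable list; CK-based densities are tumor-scope only since
# CK+ cells define the tumor compartment
canonical_variables <- function(include_fractions = TRUE) {
  dens <- c(
    "d_cd8_tumor", "d_cd8_stroma", "d_cd68_tumor", "d_cd68_stroma",
    "d_foxp3_tumor", "d_foxp3_stroma", "d_cd8_pd1_tumor", "d_cd8_pd1_stroma",
    "d_cd68_pdl1_tumor", "d_cd68_pdl1_stroma", "d_ck_tumor", "d_ck_pdl1_tumor"
  )
  frac <- c("f_pd1_cd8_tumor", "f_pd1_cd8_stroma",
            "f_pdl1_cd68_tumor", "f_pdl1_cd68_stroma", "f_pdl1_ck")
  if (include_fractions) c(dens, frac) else dens
}

#' Cores-by-variables feature matrix
#'
#' One row per core over the canonical variable list: densities of CD8, CD68,
#' FOXP3, CD8+PD-1+ and CD68+PD-L1+ cells in tumor and stroma scope, CK and
#' CK+PD-L1+ densities in tumor scope, and (optionally) the PD-1|CD8 and
#' PD-L1|CD68 fractions per scope plus the PD-L1|CK fraction — 17 variables.
#' Missing fractions (empty base population in a scope) are imputed with the
#' across-core median of the variable; densities are never missing. A core
#' with zero cells yields an all-zero density row with a warning.
#'
#' @param x A `timephen_cohort` (validated).
#' @param include_fractions Include the five fraction variables; the reference
#'   clustering pipeline uses densities only (`FALSE`) so that no imputation
#'   enters the clustering input.
#' @return A tibble with `core_id` plus one column per variable; attribute
#'   `manifest` maps each variable to its definition.
#' @export
build_feature_matrix <- function(x, include_fractions = TRUE) {
  assert_valid_cohort(x)
  prof <- core_profiles(x)
  dens <- prof |>
    dplyr::filter(.data$metric == "density",
                  .data$scope != "whole",
                  !(.data$population %in% c("ck", "ck_pdl1") & .data$scope == "stroma")) |>
    dplyr::mutate(variable = paste0("d_", .data$population, "_", .data$scope)) |>
    dplyr::select("core_id", "variable", value = "density")
  out <- dens
  if (include_fractions) {
    frac <- prof |>
      dplyr::filter(.data$metric == "fraction") |>
      dplyr::mutate(variable = dplyr::case_when(
        .data$population == "pd1_given_cd8" ~ paste0("f_pd1_cd8_", .data$scope),
        .data$population == "pdl1_given_cd68" ~ paste0("f_pdl1_cd68_", .data$scope),
        TRUE ~ "f_pdl1_ck"
      )) |>
      dplyr::select("core_id", "variable", value = "fraction") |>
      dplyr::group_by(.data$variable) |>
      dplyr::mutate(value = ifelse(is.na(.data$value),
                                   median(.data$value, na.rm = TRUE),
                                   .data$value)) |>
      dplyr::ungroup()
    frac$value[is.na(frac$value)] <- 0  # variable missing on every core
    out <- dplyr::bind_rows(dens, frac)
  }
  vars <- canonical_variables(include_fractions)
  wide <- out |>
    tidyr::pivot_wider(names_from = "variable", values_from = "value") |>
    dplyr::select("core_id", dplyr::all_of(vars)) |>
    dplyr::arrange(match(.data$core_id, x$cores$core_id))
  zero_rows <- rowSums(abs(as.matrix(wide[, grep("^d_", vars, value = TRUE)]))) == 0
  if (any(zero_rows)) {
    rlang::warn(paste0("build_feature_matrix: ", sum(zero_rows),
                       " core(s) with zero cells produced all-zero rows."))
  }
  attr(wide, "manifest") <- tibble(
    variable = vars,
    definition = c(
      "CD8+ density, tumor scope (cells/mm2)", "CD8+ density, stroma scope (cells/mm2)",
      "CD68+ density, tumor scope (cells/mm2)", "CD68+ density, stroma scope (cells/mm2)",
      "FOXP3+ density, tumor scope (cells/mm2)", "FOXP3+ density, stroma scope (cells/mm2)",
      "CD8+PD-1+ density, tumor scope (cells/mm2)", "CD8+PD-1+ density, stroma scope (cells/mm2)",
      "CD68+PD-L1+ density, tumor scope (cells/mm2)", "CD68+PD-L1+ density, stroma scope (cells/mm2)",
      "CK+ density, tumor scope (cells/mm2)", "CK+PD-L1+ density, tumor scope (cells/mm2)",
      "PD-1+ fraction of CD8+ cells, tumor", "PD-1+ fraction of CD8+ cells, stroma",
      "PD-L1+ fraction of CD68+ cells, tumor", "PD-L1+ fraction of CD68+ cells, stroma",
      "PD-L1+ fraction of CK+ cells"
    )[seq_along(vars)]
  )
  wide
}

#' Per-cluster OMD table
#'
#' Whole-core OMDs of the canonical populations for each cluster of an
#' assignment — the summary that feeds [name_clusters()].
#'
#' @param profiles Long profiles from [core_profiles()].
#' @param assignments Tibble with `core_id` and `cluster_index`.
#' @return A tibble with one row per cluster: `cluster_index`, `n_cores`, one
#'   OMD column per population, and `total_immune` (CD8 + CD68 + FOXP3 OMDs).
#' @export
cluster_omd_table <- function(profiles, assignments) {
  profiles |>
    dplyr::filter(.data$metric == "density", .data$scope == "whole") |>
    dplyr::inner_join(assignments[, c("core_id", "cluster_index")], by = "core_id") |>
    dplyr::group_by(.data$cluster_index, .data$population) |>
    dplyr::summarise(omd = median(.data$density),
                     n_cores = dplyr::n(), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "population", values_from = "omd") |>
    dplyr::mutate(total_immune = .data$cd8 + .data$cd68 + .data$foxp3)
}
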