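# Seeded generator of synthetic TMA cohorts with known ground truth.
#
# Geometry: a core is a disc of the stated diameter (default 1.2 mm) with the
# bounding-box origin at its top-left corner, x/y in micrometers, y increasing
# downward (image convention). Tumor (CK+) cells follow a Thomas-type
# parent-offspring clustered point process confined to circular "nests" around
# the parents; the nest union is the tumor-compartment mask. Immune cells are
# homogeneous Poisson over the disc at whole-core target intensity and receive
# the compartment of the mask region containing them.

ARCHETYPE_NAMES <- c("immune_desert", "til_rich", "immune_exclusion",
                     "foxp3_rich", "macrophage_rich")

#' Default immune-phenotype archetypes
#'
#' One row per archetype: whole-core density targets (cells/mm^2) for the four
#' lineage populations, conditional marker-positivity rates, tumor-nest
#' geometry, and the derived CK+PD-L1+ density target
#' (`ck_pdl1 = ck * pdl1_given_ck`). Density targets reported for the published
#' TMA cohort are used verbatim; every other value is an invented default
#' chosen to reproduce the qualitative contrasts between phenotypes (see the
#' methods vignette). [archetype_provenance()] flags each field per archetype
#' as `printed`, `derived` or `invented`.
#'
#' @return A tibble with one row per archetype.
#' @export
default_archetypes <- function() {
  a <- tibble(
    name = ARCHETYPE_NAMES,
    # whole-core density targets, cells/mm^2
    ck    = c(3500, 3500, 6445.38 / 0.80, 3500, 3500),
    cd8   = c(109.63, 695.45, 106.87, 300, 300),
    cd68  = c(134.32, 250, 200, 250, 700),
    foxp3 = c(15, 40, 20, 180, 40),
    # conditional marker rates
    pd1_given_cd8_tumor   = c(0.15, 0.55, 0.30, 0.22, 0.30),
    pd1_given_cd8_stroma  = c(0.10, 0.30, 0.20, 0.25, 0.20),
    pdl1_given_ck         = c(0.02, 0.10, 0.80, 0.25, 0.25),
    pdl1_given_cd68_tumor = c(0.10, 0.35, 0.60, 0.45, 0.45),
    pdl1_given_cd68_stroma = c(0.08, 0.30, 0.25, 0.35, 0.35),
    # spatial structure: nest parents per core and fraction of core area that
    # is tumor; immune-exclusion gets more, tighter nests (higher tumor-cell
    # packing) than the other phenotypes
    tumor_fraction = c(0.45, 0.40, 0.60, 0.45, 0.45),
    nest_parent_mean = c(10, 10, 22, 10, 10)
  )
  dplyr::mutate(a, ck_pdl1 = .data$ck * .data$pdl1_given_ck)
}

#' @rdname default_archetypes
#' @export
archetype_provenance <- function() {
  printed <- tibble(
    archetype = c("immune_desert", "immune_desert", "til_rich",
                  "immune_exclusion", "immune_exclusion"),
    field = c("cd8", "cd68", "cd8", "cd8", "ck_pdl1"),
    source = "printed"
  )
  a <- default_archetypes()
  fields <- setdiff(names(a), "name")
  all <- tidyr::expand_grid(archetype = a$name, field = fields)
  all <- dplyr::anti_join(all, printed, by = c("archetype", "field"))
  derived <- all$field %in% "ck_pdl1" |
    (all$archetype == "immune_exclusion" & all$field == "ck")
  all$source <- ifelse(derived, "derived", "invented")
  dplyr::arrange(dplyr::bind_rows(printed, all), .data$archetype, .data$field)
}

# purity log-odds increment that holds the carrier-average relapse probability
# at `p_carrier` given the mixed-carrier probability and the carriage geometry
solve_purity_beta <- function(q, f2, rep_prob, p_mixed, p_carrier, beta0, beta_carriage) {
  both <- q * (rep_prob + (1 - rep_prob) * q)
  none_two <- (1 - q) * (rep_prob + (1 - rep_prob) * (1 - q))
  w_pure <- (1 - f2) * q + f2 * both
  w_mixed <- f2 * (1 - none_two - both)
  p_pure <- ((w_pure + w_mixed) * p_carrier - w_mixed * p_mixed) / w_pure
  stopifnot(p_pure > 0, p_pure < 1)
  qlogis(p_pure) - (beta0 + beta_carriage)
}

#' Synthetic-cohort configuration
#'
#' Defaults reproduce the published cohort's margins: 235 patients of whom
#' 169/235 contribute two analyzable cores (404 cores in total), archetype
#' shares (279, 18, 78, 14, 15)/404, background relapse probability 0.012,
#' an average relapse probability of 0.48 among carriers of an
#' immune-exclusion core (split into a carriage effect and a purity effect —
#' relapse is more likely again when every analyzed core is immune-exclusion),
#' relapse times lognormal with median 31 months, and non-relapse follow-up
#' capped at 120 months with a 6.7% short-follow-up (< 36 months) fraction.
#'
#' @param n_patients Number of patients.
#' @param two_core_fraction Probability that a patient contributes two cores.
#' @param cluster_mixture Length-5 probability vector over archetypes (order of
#'   [default_archetypes()]).
#' @param outcome_beta0 Intercept of the relapse model on the logit scale.
#' @param outcome_beta_exclusion Log-odds increment for immune-exclusion
#'   carriage (mixed carriers: at least one exclusion core but not all).
#' @param outcome_beta_purity Additional log-odds increment when every
#'   analyzed core is immune-exclusion (single-core exclusion patients count
#'   as pure). The default is solved so the carrier-average relapse
#'   probability equals 0.48 under the default mixture and carriage geometry.
#' @param archetype_repeat Probability that a second core repeats the first
#'   core's archetype (within-patient correlation); otherwise redrawn from the
#'   mixture.
#' @param short_followup_rate Fraction of non-relapsers lost to follow-up
#'   before 36 months.
#' @param rng_seed Integer seed; the generator is fully deterministic given the
#'   configuration.
#' @return A list of class `timephen_config`.
#' @export
synthetic_config <- function(n_patients = 235,
                             two_core_fraction = 169 / 235,
                             cluster_mixture = c(279, 18, 78, 14, 15) / 404,
                             outcome_beta0 = qlogis(0.012),
                             outcome_beta_exclusion = qlogis(0.25) - qlogis(0.012),
                             outcome_beta_purity = NULL,
                             archetype_repeat = 0.7,
                             short_followup_rate = 0.067,
                             rng_seed = 1L) {
  stopifnot(n_patients >= 1, length(cluster_mixture) == 5,
            abs(sum(cluster_mixture) - 1) < 1e-8, all(cluster_mixture >= 0),
            two_core_fraction >= 0, two_core_fraction <= 1)
  if (is.null(outcome_beta_purity)) {
    outcome_beta_purity <- solve_purity_beta(
      q = cluster_mixture[3], f2 = two_core_fraction, rep_prob = archetype_repeat,
      p_mixed = plogis(outcome_beta0 + outcome_beta_exclusion),
      p_carrier = 0.48, beta0 = outcome_beta0, beta_carriage = outcome_beta_exclusion
    )
  }
  structure(list(
    n_patients = as.integer(n_patients), two_core_fraction = two_core_fraction,
    cluster_mixture = cluster_mixture, outcome_beta0 = outcome_beta0,
    outcome_beta_exclusion = outcome_beta_exclusion,
    outcome_beta_purity = outcome_beta_purity,
    archetype_repeat = archetype_repeat,
    short_followup_rate = short_followup_rate, rng_seed = as.integer(rng_seed)
  ), class = "timephen_config")
}

# uniform points in a disc of radius r centered at (r, r)
runif_disc <- function(n, radius) {
  theta <- runif(n, 0, 2 * pi)
  rad <- radius * sqrt(runif(n))
  tibble(x = radius + rad * cos(theta), y = radius + rad * sin(theta))
}

#' Generate the cells of one synthetic core
#'
#' Places CK+ tumor cells by a parent-offspring clustered process inside
#' circular tumor nests and immune cells (CD8, CD68, FOXP3) by homogeneous
#' Poisson processes over the core disc, then samples PD-1/PD-L1 positivity
#' from the archetype's conditional rates. The expected whole-core count of
#' each population equals its density target times the core area. Uses the
#' current RNG state; seed upstream (see [generate_cohort()]) for
#' reproducibility.
#'
#' @param archetype A single row of [default_archetypes()].
#' @param core A single row of core metadata (`core_id`, `diameter_mm`,
#'   `area_mm2`).
#' @return A tibble of cells in the canonical schema.
#' @export
generate_core <- function(archetype, core) {
  stopifnot(nrow(archetype) == 1, nrow(core) == 1)
  if (!is.finite(core$area_mm2) || core$area_mm2 <= 0) {
    rlang::abort("generate_core: core area must be positive.")
  }
  radius_um <- core$diameter_mm / 2 * 1000
  area_um2 <- pi * radius_um^2

  # tumor nests: parent centres uniform in the disc; nest radius set so the
  # summed nest area (overlap ignored) matches the archetype tumor fraction
  n_parents <- max(1L, rpois(1, archetype$nest_parent_mean))
  parents <- runif_disc(n_parents, radius_um)
  nest_radius <- sqrt(archetype$tumor_fraction * area_um2 / (n_parents * pi))
  sigma <- nest_radius / 2.5

  in_mask <- function(x, y) {
    inside <- rep(FALSE, length(x))
    for (p in seq_len(n_parents)) {
      inside <- inside | ((x - parents$x[p])^2 + (y - parents$y[p])^2 <= nest_radius^2)
    }
    inside
  }

  # CK+ tumor cells: Gaussian offspring truncated to the parent's nest and the
  # core disc (re-drawn until inside, which preserves the expected count)
  n_ck <- rpois(1, archetype$ck * core$area_mm2)
  ck_xy <- tibble(x = numeric(0), y = numeric(0))
  if (n_ck > 0) {
    todo <- n_ck
    xs <- numeric(0); ys <- numeric(0)
    while (todo > 0) {
      p <- sample.int(n_parents, todo, replace = TRUE)
      x <- parents$x[p] + rnorm(todo, 0, sigma)
      y <- parents$y[p] + rnorm(todo, 0, sigma)
      ok <- ((x - parents$x[p])^2 + (y - parents$y[p])^2 <= nest_radius^2) &
        ((x - radius_um)^2 + (y - radius_um)^2 <= radius_um^2)
      xs <- c(xs, x[ok]); ys <- c(ys, y[ok])
      todo <- todo - sum(ok)
    }
    ck_xy <- tibble(x = xs, y = ys)
  }

  immune <- purrr::map(c(cd8 = "cd8", cd68 = "cd68", foxp3 = "foxp3"), function(pop) {
    n <- rpois(1, archetype[[pop]] * core$area_mm2)
    runif_disc(n, radius_um)
  })

  lineage <- c(rep("ck", nrow(ck_xy)), rep("cd8", nrow(immune$cd8)),
               rep("cd68", nrow(immune$cd68)), rep("foxp3", nrow(immune$foxp3)))
  xy <- dplyr::bind_rows(ck_xy, immune$cd8, immune$cd68, immune$foxp3)
  n_total <- nrow(xy)
  if (n_total == 0) {
    return(tibble(cell_id = character(), core_id = character(),
                  x_um = numeric(), y_um = numeric(), compartment = character(),
                  ck = logical(), cd8 = logical(), cd68 = logical(),
                  foxp3 = logical(), pd1 = logical(), pdl1 = logical()))
  }
  compartment <- ifelse(lineage == "ck" | in_mask(xy$x, xy$y), "tumor", "stroma")

  pd1 <- rep(FALSE, n_total)
  pdl1 <- rep(FALSE, n_total)
  is_cd8 <- lineage == "cd8"
  pd1[is_cd8] <- runif(sum(is_cd8)) < ifelse(compartment[is_cd8] == "tumor",
                                             archetype$pd1_given_cd8_tumor,
                                             archetype$pd1_given_cd8_stroma)
  is_ck <- lineage == "ck"
  pdl1[is_ck] <- runif(sum(is_ck)) < archetype$pdl1_given_ck
  is_cd68 <- lineage == "cd68"
  pdl1[is_cd68] <- runif(sum(is_cd68)) < ifelse(compartment[is_cd68] == "tumor",
                                                archetype$pdl1_given_cd68_tumor,
                                                archetype$pdl1_given_cd68_stroma)

  tibble(
    cell_id = paste0(core$core_id, "_", seq_len(n_total)),
    core_id = core$core_id,
    x_um = xy$x, y_um = xy$y, compartment = compartment,
    ck = lineage == "ck", cd8 = is_cd8, cd68 = is_cd68,
    foxp3 = lineage == "foxp3", pd1 = pd1, pdl1 = pdl1
  )
}

# patient-level margin shared by generate_cohort() and
# simulate_patient_features(): archetype draws, clinical covariates, outcome
draw_patient_level <- function(config) {
  n <- config$n_patients
  two_core <- runif(n) < config$two_core_fraction
  arch1 <- sample(ARCHETYPE_NAMES, n, replace = TRUE, prob = config$cluster_mixture)
  repeat_first <- runif(n) < config$archetype_repeat
  arch2 <- ifelse(repeat_first, arch1,
                  sample(ARCHETYPE_NAMES, n, replace = TRUE, prob = config$cluster_mixture))
  arch2[!two_core] <- NA_character_

  carrier <- arch1 == "immune_exclusion" | (!is.na(arch2) & arch2 == "immune_exclusion")
  pure <- ifelse(two_core,
                 arch1 == "immune_exclusion" & arch2 == "immune_exclusion",
                 arch1 == "immune_exclusion")
  p_relapse <- plogis(config$outcome_beta0 +
                        config$outcome_beta_exclusion * carrier +
                        config$outcome_beta_purity * pure)
  relapse <- runif(n) < p_relapse

  followup <- numeric(n)
  n_rel <- sum(relapse)
  followup[relapse] <- pmin(120, rlnorm(n_rel, log(31), 0.72))
  nr <- !relapse
  short <- nr & runif(n) < config$short_followup_rate
  followup[short] <- runif(sum(short), 6, 35.9)
  long <- nr & !short
  followup[long] <- pmax(36, pmin(120, rnorm(sum(long), 125, 30)))

  relapse_type <- rep("none", n)
  relapse_type[relapse] <- sample(c("distant", "node", "local"), n_rel,
                                  replace = TRUE, prob = c(16, 12, 11) / 39)

  tibble(
    patient_id = sprintf("P%04d", seq_len(n)),
    figo_stage = sample(c("IA", "IB", "II"), n, replace = TRUE, prob = c(0.80, 0.15, 0.05)),
    grade = sample(c("G1", "G2"), n, replace = TRUE, prob = c(0.70, 0.30)),
    lvsi = runif(n) < 0.12,
    adjuvant_rt = sample(c("none", "EBRT", "VBT", "both", "unknown"), n,
                         replace = TRUE, prob = c(0.643, 0.090, 0.135, 0.042, 0.090)),
    mmrp_deficient = sample(c("yes", "no", "unknown"), n, replace = TRUE,
                            prob = c(0.158, 0.792, 0.050)),
    pole_mutated = sample(c("yes", "no", "unknown"), n, replace = TRUE,
                          prob = c(0.023, 0.777, 0.200)),
    ctnnb1_mutated = sample(c("yes", "no", "unknown"), n, replace = TRUE,
                            prob = c(0.130, 0.770, 0.100)),
    relapse = relapse, relapse_type = relapse_type, followup_months = followup,
    two_core = two_core, archetype_core1 = arch1, archetype_core2 = arch2,
    p_relapse = p_relapse
  )
}

#' Generate a full synthetic cohort with ground truth
#'
#' Draws the patient level (core count, per-core archetypes with within-patient
#' correlation, clinical covariates, relapse outcome and follow-up), then
#' generates every core's cells with [generate_core()]. Fully deterministic
#' given the configuration (including its `rng_seed`).
#'
#' @param config A [synthetic_config()].
#' @param archetypes Archetype table, by default [default_archetypes()].
#' @return A `timephen_cohort` whose extra element `truth` holds the planted
#'   core archetypes (`truth$cores`) and patient-level relapse model
#'   (`truth$patients`).
#' @export
generate_cohort <- function(config = synthetic_config(), archetypes = default_archetypes()) {
  stopifnot(inherits(config, "timephen_config"))
  set.seed(config$rng_seed)
  pl <- draw_patient_level(config)

  cores <- pl |>
    dplyr::select("patient_id", "two_core", "archetype_core1", "archetype_core2") |>
    tidyr::pivot_longer(c("archetype_core1", "archetype_core2"),
                        names_to = "slot", values_to = "archetype") |>
    dplyr::filter(!is.na(.data$archetype)) |>
    dplyr::mutate(core_id = paste0(.data$patient_id, "_c",
                                   ifelse(.data$slot == "archetype_core1", 1L, 2L)),
                  diameter_mm = 1.2, area_mm2 = pi * 0.6^2) |>
    dplyr::select("core_id", "patient_id", "diameter_mm", "area_mm2", "archetype")

  cells <- purrr::map(seq_len(nrow(cores)), function(i) {
    generate_core(archetypes[archetypes$name == cores$archetype[i], ], cores[i, ])
  }) |> dplyr::bind_rows()

  out <- cohort(
    cells = cells,
    cores = dplyr::select(cores, -"archetype"),
    patients = dplyr::select(pl, -"two_core", -"archetype_core1",
                             -"archetype_core2", -"p_relapse")
  )
  out$truth <- list(
    cores = dplyr::select(cores, "core_id", "archetype"),
    patients = dplyr::select(pl, "patient_id", "archetype_core1",
                             "archetype_core2", "p_relapse")
  )
  out
}

#' Simulate the generator's patient-level margin only
#'
#' Draws per-core archetypes, clinical covariates and relapse outcomes from the
#' same model as [generate_cohort()] but skips cell placement, returning a
#' patient feature table with ground-truth carriage/purity indicators directly.
#' Useful when many replicate cohorts are needed and only the outcome layer is
#' under study.
#'
#' @param config A [synthetic_config()].
#' @return A tibble shaped like the output of [aggregate_patients()], plus the
#'   planted relapse probability `p_relapse`.
#' @export
simulate_patient_features <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "timephen_config"))
  set.seed(config$rng_seed)
  pl <- draw_patient_level(config)
  for (a in ARCHETYPE_NAMES) {
    hit1 <- pl$archetype_core1 == a
    hit2 <- !is.na(pl$archetype_core2) & pl$archetype_core2 == a
    pl[[paste0("carriage_", a)]] <- hit1 | hit2
    pl[[paste0("purity_", a)]] <- ifelse(pl$two_core, hit1 & hit2, hit1)
  }
  pl |>
    dplyr::mutate(n_cores = ifelse(.data$two_core, 2L, 1L)) |>
    dplyr::select("patient_id", "figo_stage", "grade", "lvsi", "adjuvant_rt",
                  "mmrp_deficient", "pole_mutated", "ctnnb1_mutated",
                  dplyr::starts_with("carriage_"), dplyr::starts_with("purity_"),
                  "n_cores", "relapse", "relapse_type", "followup_months",
                  "p_relapse")
}
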