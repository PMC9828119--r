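# Fixture builders shared across test files. Everything is generated in code;
# no data files.

# a minimal valid cell tibble
make_cells <- function(n = 10, core_id = "c1", seed = 1) {
  set.seed(seed)
  lineage <- sample(c("ck", "cd8", "cd68", "foxp3"), n, replace = TRUE)
  tibble::tibble(
    cell_id = paste0(core_id, "_", seq_len(n)),
    core_id = core_id,
    x_um = runif(n, 0, 1200), y_um = runif(n, 0, 1200),
    compartment = sample(c("tumor", "stroma"), n, replace = TRUE),
    ck = lineage == "ck", cd8 = lineage == "cd8", cd68 = lineage == "cd68",
    foxp3 = lineage == "foxp3",
    pd1 = runif(n) < 0.3, pdl1 = runif(n) < 0.3
  )
}

make_patient_row <- function(patient_id, relapse = FALSE, followup = 60,
                             relapse_type = if (relapse) "distant" else "none") {
  tibble::tibble(
    patient_id = patient_id, figo_stage = "IA", grade = "G1", lvsi = FALSE,
    adjuvant_rt = "none", mmrp_deficient = "no", pole_mutated = "no",
    ctnnb1_mutated = "no", relapse = relapse, relapse_type = relapse_type,
    followup_months = followup
  )
}

make_small_cohort <- function(n_patients = 3, cells_per_core = 10, seed = 1) {
  patients <- dplyr::bind_rows(lapply(sprintf("P%02d", seq_len(n_patients)),
                                      make_patient_row))
  cores <- tibble::tibble(
    core_id = paste0(patients$patient_id, "_c1"),
    patient_id = patients$patient_id,
    diameter_mm = 1.2, area_mm2 = pi * 0.6^2
  )
  cells <- dplyr::bind_rows(lapply(seq_len(n_patients), function(i) {
    make_cells(cells_per_core, core_id = cores$core_id[i], seed = seed + i)
  }))
  cohort(cells, cores, patients)
}

# Deterministic patient/assignment fixture mirroring the published cohort's
# printed margins: 169 two-core + 66 one-core patients (404 cores), core
# phenotype counts (279 desert, 18 TIL-rich, 78 exclusion, 14 FOXP3-rich,
# 15 macrophage-rich), 14 short-follow-up non-relapsers excluded, 52 retained
# exclusion carriers of whom 25 relapse, plus 2 relapses in non-carriers.
make_printed_margin_fixture <- function() {
  two_core_ids <- sprintf("P%03d", 1:169)
  one_core_ids <- sprintf("P%03d", 170:235)
  cores <- dplyr::bind_rows(
    tibble::tibble(core_id = c(paste0(two_core_ids, "_c1"), paste0(two_core_ids, "_c2")),
                   patient_id = rep(two_core_ids, 2)),
    tibble::tibble(core_id = paste0(one_core_ids, "_c1"), patient_id = one_core_ids)
  ) |>
    dplyr::mutate(diameter_mm = 1.2, area_mm2 = pi * 0.6^2) |>
    dplyr::arrange(patient_id, core_id)

  # exclusion carriers: patients 1..26 (both cores) and 170..195 (single core)
  carriers_two <- sprintf("P%03d", 1:26)
  carriers_one <- sprintf("P%03d", 170:195)
  exclusion_cores <- c(paste0(carriers_two, "_c1"), paste0(carriers_two, "_c2"),
                       paste0(carriers_one, "_c1"))
  stopifnot(length(exclusion_cores) == 78)
  other_cores <- setdiff(cores$core_id, exclusion_cores)
  other_names <- rep(c("immune_desert", "til_rich", "foxp3_rich", "macrophage_rich"),
                     c(279, 18, 14, 15))
  stopifnot(length(other_cores) == length(other_names))
  assignments <- dplyr::bind_rows(
    tibble::tibble(core_id = exclusion_cores, semantic_name = "immune_exclusion"),
    tibble::tibble(core_id = other_cores, semantic_name = other_names)
  )

  relapse_carriers <- sprintf("P%03d", c(1:20, 170:174))   # 25 carrier relapses
  relapse_noncarriers <- sprintf("P%03d", 60:61)           # 2 non-carrier relapses
  excluded_short <- sprintf("P%03d", 100:113)              # 14 short follow-up
  patients <- dplyr::bind_rows(lapply(c(two_core_ids, one_core_ids), function(p) {
    if (p %in% c(relapse_carriers, relapse_noncarriers)) {
      make_patient_row(p, relapse = TRUE, followup = 24)
    } else if (p %in% excluded_short) {
      make_patient_row(p, relapse = FALSE, followup = 20)
    } else {
      make_patient_row(p, relapse = FALSE, followup = 90)
    }
  }))
  list(cohort = cohort(cells = make_cells(0), cores = cores, patients = patients),
       assignments = assignments)
}

# an archetype row with chosen densities, other fields from the named default
archetype_row <- function(base = "immune_desert", ...) {
  a <- default_archetypes()
  row <- a[a$name == base, ]
  mods <- list(...)
  for (nm in names(mods)) row[[nm]] <- mods[[nm]]
  row
}

default_core_meta <- function(core_id = "core1") {
  tibble::tibble(core_id = core_id, patient_id = "P1",
                 diameter_mm = 1.2, area_mm2 = pi * 0.6^2)
}

# brute-force O(n^2) neighbor adjacency oracle
brute_force_edges <- function(cells, radius_um) {
  n <- nrow(cells)
  out <- list()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d2 <- (cells$x_um[i] - cells$x_um[j])^2 + (cells$y_um[i] - cells$y_um[j])^2
      if (d2 <= radius_um^2) out[[length(out) + 1]] <- c(i, j)
    }
  }
  if (length(out) == 0) return(tibble::tibble(i = integer(), j = integer()))
  m <- do.call(rbind, out)
  tibble::tibble(i = m[, 1], j = m[, 2])
}

# exhaustive pair-counting AUC oracle (half credit for ties)
pair_count_auc <- function(scores, y) {
  pos <- scores[y == 1]; neg <- scores[y == 0]
  total <- 0
  for (p in pos) for (q in neg) total <- total + (p > q) + 0.5 * (p == q)
  total / (length(pos) * length(neg))
}
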