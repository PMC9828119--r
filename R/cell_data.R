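# Data model and I/O for per-cell tables, core metadata and patient clinical
# tables. All readers are dialect-driven: a dialect maps source column names and
# value encodings onto the canonical schema, so inForm-style exports and the
# package's own canonical files go through the same code path.

#' Column dialects for cell-table ingestion
#'
#' A dialect describes how a source file's columns and value encodings map onto
#' the canonical cell schema: `columns` maps canonical field -> source header,
#' `true_values`/`false_values` list accepted boolean encodings, and
#' `compartment_aliases` maps source compartment labels to `"tumor"`/`"stroma"`.
#'
#' `canonical_dialect()` reads files written by [write_cohort()].
#' `inform_dialect()` reads a typical image-analysis per-cell export with
#' `Cell ID`/`Cell X Position`-style headers, `Tumor`/`Stroma`/`Tumour` tissue
#' categories and `+`/`-` marker calls.
#'
#' @return A list of class `timephen_dialect`.
#' @export
canonical_dialect <- function() {
  structure(list(
    name = "canonical",
    delim = "\t",
    columns = c(
      cell_id = "cell_id", core_id = "core_id", x_um = "x_um", y_um = "y_um",
      compartment = "compartment", ck = "ck", cd8 = "cd8", cd68 = "cd68",
      foxp3 = "foxp3", pd1 = "pd1", pdl1 = "pdl1"
    ),
    true_values = c("1", "true", "TRUE", "True", "+", "yes"),
    false_values = c("0", "false", "FALSE", "False", "-", "−", "no"),
    compartment_aliases = c(
      tumor = "tumor", stroma = "stroma"
    )
  ), class = "timephen_dialect")
}

#' @rdname canonical_dialect
#' @export
inform_dialect <- function() {
  d <- canonical_dialect()
  d$name <- "inform-like"
  d$columns <- c(
    cell_id = "Cell ID", core_id = "Sample Name",
    x_um = "Cell X Position", y_um = "Cell Y Position",
    compartment = "Tissue Category",
    ck = "CK", cd8 = "CD8", cd68 = "CD68", foxp3 = "FOXP3",
    pd1 = "PD-1", pdl1 = "PD-L1"
  )
  d$compartment_aliases <- c(
    tumor = "tumor", Tumor = "tumor", Tumour = "tumor", tumour = "tumor",
    stroma = "stroma", Stroma = "stroma"
  )
  d
}

#' Read a dialect definition from a YAML file
#'
#' The YAML file may carry any subset of the dialect fields; missing fields are
#' filled from [canonical_dialect()].
#'
#' @param path Path to a YAML dialect file.
#' @return A `timephen_dialect` list.
#' @export
read_dialect <- function(path) {
  cfg <- yaml::read_yaml(path)
  d <- canonical_dialect()
  for (field in intersect(names(cfg), names(d))) {
    value <- cfg[[field]]
    d[[field]] <- if (field %in% c("columns", "compartment_aliases")) {
      unlist(value)
    } else {
      value
    }
  }
  d$name <- cfg$name %||% "custom"
  d
}

decode_boolean <- function(x, dialect) {
  x_chr <- trimws(as.character(x))
  out <- rep(NA, length(x_chr))
  out[x_chr %in% dialect$true_values] <- TRUE
  out[x_chr %in% dialect$false_values] <- FALSE
  as.logical(out)
}

#' Read a per-cell table
#'
#' Parses a delimiter-separated per-cell export into the canonical cell schema
#' (one row per segmented cell: identifiers, x/y position in micrometers,
#' tumor/stroma compartment, six boolean marker channels). Rows whose
#' coordinates, compartment or marker calls cannot be parsed are rejected, not
#' silently dropped: the returned tibble carries a `rejections` attribute (a
#' tibble of row numbers and reasons) and the rejection count is reported.
#'
#' @param path Path to the delimited file.
#' @param dialect A `timephen_dialect`, e.g. [canonical_dialect()] or
#'   [inform_dialect()].
#' @param quiet Suppress the rejection message.
#' @return A tibble of cells with attribute `rejections`.
#' @export
read_cell_table <- function(path, dialect = canonical_dialect(), quiet = FALSE) {
  stopifnot(file.exists(path))
  raw <- readr::read_delim(path, delim = dialect$delim, col_types = readr::cols(.default = "c"),
                           progress = FALSE, show_col_types = FALSE)
  missing_cols <- setdiff(unname(dialect$columns), names(raw))
  if (length(missing_cols) > 0) {
    rlang::abort(paste0("Mandatory column(s) missing from ", path, ": ",
                        paste(missing_cols, collapse = ", ")))
  }
  src <- raw[, unname(dialect$columns)]
  names(src) <- names(dialect$columns)

  x <- suppressWarnings(as.numeric(src$x_um))
  y <- suppressWarnings(as.numeric(src$y_um))
  comp <- unname(dialect$compartment_aliases[trimws(src$compartment)])
  markers <- lapply(.all_markers, function(m) decode_boolean(src[[m]], dialect))
  names(markers) <- .all_markers

  reasons <- character(nrow(src))
  bad_coord <- !is.finite(x) | !is.finite(y) | x < 0 | y < 0
  bad_comp <- is.na(comp)
  bad_marker <- Reduce(`|`, lapply(markers, is.na))
  reasons[bad_marker] <- "unparseable marker call"
  reasons[bad_comp] <- "unknown compartment label"
  reasons[bad_coord] <- "unparseable or negative coordinate"
  reject <- reasons != ""

  cells <- tibble(
    cell_id = as.character(src$cell_id),
    core_id = as.character(src$core_id),
    x_um = x, y_um = y, compartment = comp,
    ck = markers$ck, cd8 = markers$cd8, cd68 = markers$cd68,
    foxp3 = markers$foxp3, pd1 = markers$pd1, pdl1 = markers$pdl1
  )[!reject, ]
  rejections <- tibble(row = which(reject), reason = reasons[reject])
  if (!quiet && nrow(rejections) > 0) {
    rlang::inform(paste0("read_cell_table: rejected ", nrow(rejections), " row(s) of ",
                         nrow(src), " from ", basename(path)))
  }
  attr(cells, "rejections") <- rejections
  cells
}

#' Read core metadata and patient clinical tables
#'
#' Companions of [read_cell_table()] for the other two cohort files. Both are
#' strict: a malformed row is a hard error, since these tables are small and
#' hand-curated.
#'
#' @param path Path to a tab-separated file.
#' @return A tibble (`cores` or `patients` schema).
#' @export
read_core_table <- function(path) {
  stopifnot(file.exists(path))
  x <- readr::read_tsv(path, col_types = readr::cols(
    core_id = "c", patient_id = "c", diameter_mm = "d", area_mm2 = "d"
  ), progress = FALSE, show_col_types = FALSE)
  stopifnot(all(c("core_id", "patient_id", "diameter_mm", "area_mm2") %in% names(x)))
  if (any(!is.finite(x$area_mm2) | x$area_mm2 <= 0)) {
    rlang::abort("read_core_table: non-positive or missing core area.")
  }
  x
}

#' @rdname read_core_table
#' @export
read_patient_table <- function(path) {
  stopifnot(file.exists(path))
  x <- readr::read_tsv(path, col_types = readr::cols(
    patient_id = "c", figo_stage = "c", grade = "c", lvsi = "l",
    adjuvant_rt = "c", mmrp_deficient = "c", pole_mutated = "c",
    ctnnb1_mutated = "c", relapse = "l", relapse_type = "c",
    followup_months = "d"
  ), progress = FALSE, show_col_types = FALSE)
  stopifnot(all(c("patient_id", "figo_stage", "grade", "lvsi", "adjuvant_rt",
                  "relapse", "relapse_type", "followup_months") %in% names(x)))
  x
}

#' Assemble a cohort object
#'
#' A cohort bundles the three tables the pipeline operates on: per-cell
#' records, per-core metadata and per-patient clinical data.
#'
#' @param cells Tibble of cells (canonical schema).
#' @param cores Tibble of core metadata.
#' @param patients Tibble of patient clinical records.
#' @return An object of class `timephen_cohort`.
#' @export
cohort <- function(cells, cores, patients) {
  structure(list(cells = as_tibble(cells), cores = as_tibble(cores),
                 patients = as_tibble(patients)),
            class = "timephen_cohort")
}

#' @export
print.timephen_cohort <- function(x, ...) {
  cat("<timephen_cohort> ", nrow(x$cells), " cells, ", nrow(x$cores),
      " cores, ", nrow(x$patients), " patients\n", sep = "")
  invisible(x)
}

#' Validate a cohort against the data-model invariants
#'
#' Checks referential integrity (every cell's core exists, every core's patient
#' exists), the two-cores-per-patient cap, lineage exclusivity (at most one of
#' CK/CD8/CD68/FOXP3 positive per cell; PD-1/PD-L1 may co-occur with any
#' lineage), coordinate sanity, relapse/relapse-type consistency and
#' non-negative follow-up. Returns a report rather than erroring; downstream
#' stages call [assert_valid_cohort()] to refuse invalid input.
#'
#' @param x A `timephen_cohort`.
#' @param resolve_lineage If `TRUE`, lineage co-positive cells are resolved by
#'   the priority CK > CD8 > CD68 > FOXP3 instead of being reported as
#'   violations; the resolved cohort is attached to the report as
#'   `attr(, "cohort")`.
#' @return A tibble with columns `check`, `id`, `detail`, one row per
#'   violation; zero rows means the cohort is valid.
#' @export
validate_cohort <- function(x, resolve_lineage = FALSE) {
  stopifnot(inherits(x, "timephen_cohort"))
  v <- list()
  orphan_cells <- setdiff(unique(x$cells$core_id), x$cores$core_id)
  if (length(orphan_cells) > 0) {
    v$orphan <- tibble(check = "cell_core_exists", id = orphan_cells,
                       detail = "cells reference a core_id absent from cores")
  }
  orphan_cores <- x$cores$patient_id[!x$cores$patient_id %in% x$patients$patient_id]
  if (length(orphan_cores) > 0) {
    v$orphan_core <- tibble(check = "core_patient_exists", id = unique(orphan_cores),
                            detail = "cores reference a patient_id absent from patients")
  }
  per_patient <- dplyr::count(x$cores, .data$patient_id)
  over <- per_patient$patient_id[per_patient$n > 2]
  if (length(over) > 0) {
    v$cores_per_patient <- tibble(check = "max_two_cores", id = over,
                                  detail = "more than two cores for one patient")
  }
  if (nrow(x$cells) > 0) {
    n_lineage <- rowSums(as.matrix(x$cells[, .lineage_markers]))
    multi <- which(n_lineage > 1)
    if (length(multi) > 0 && resolve_lineage) {
      cells <- x$cells
      lin <- as.matrix(cells[multi, .lineage_markers])
      first <- apply(lin, 1, which.max)  # CK > CD8 > CD68 > FOXP3 priority
      for (j in seq_along(multi)) {
        cells[multi[j], .lineage_markers] <- as.list(seq_len(4) == first[j])
      }
      x$cells <- cells
      multi <- integer(0)
    }
    if (length(multi) > 0) {
      v$lineage <- tibble(check = "lineage_exclusivity",
                          id = as.character(x$cells$cell_id[multi]),
                          detail = "more than one lineage marker positive")
    }
    bad_xy <- which(!is.finite(x$cells$x_um) | !is.finite(x$cells$y_um) |
                      x$cells$x_um < 0 | x$cells$y_um < 0)
    if (length(bad_xy) > 0) {
      v$coord <- tibble(check = "coordinates", id = as.character(x$cells$cell_id[bad_xy]),
                        detail = "non-finite or negative coordinate")
    }
  }
  if (nrow(x$patients) > 0) {
    bad_rt <- which(!x$patients$relapse & x$patients$relapse_type != "none")
    if (length(bad_rt) > 0) {
      v$relapse <- tibble(check = "relapse_type_consistency",
                          id = x$patients$patient_id[bad_rt],
                          detail = "relapse_type set for non-relapsed patient")
    }
    bad_fu <- which(x$patients$followup_months < 0)
    if (length(bad_fu) > 0) {
      v$fu <- tibble(check = "followup_nonnegative", id = x$patients$patient_id[bad_fu],
                     detail = "negative follow-up")
    }
  }
  report <- if (length(v) == 0) {
    tibble(check = character(), id = character(), detail = character())
  } else {
    dplyr::bind_rows(v)
  }
  attr(report, "cohort") <- x
  report
}

#' @rdname validate_cohort
#' @export
assert_valid_cohort <- function(x) {
  report <- validate_cohort(x)
  if (nrow(report) > 0) {
    rlang::abort(paste0("Invalid cohort: ", nrow(report), " violation(s); first: ",
                        report$check[1], " (", report$id[1], ")"))
  }
  invisible(x)
}

#' Write / re-read a cohort as three tab-separated files
#'
#' `write_cohort()` writes `cells.tsv`, `cores.tsv` and `patients.tsv` into a
#' directory; `read_cohort()` reloads them into an identical cohort (booleans
#' round-trip bitwise, coordinates at full double precision).
#'
#' @param x A `timephen_cohort`.
#' @param dir Output directory (created if absent).
#' @return `write_cohort()` the file paths invisibly; `read_cohort()` a
#'   `timephen_cohort`.
#' @export
write_cohort <- function(x, dir) {
  stopifnot(inherits(x, "timephen_cohort"))
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) rlang::abort(paste0("Cannot create directory: ", dir))
  }
  paths <- file.path(dir, c("cells.tsv", "cores.tsv", "patients.tsv"))
  fmt <- function(df) {
    dplyr::mutate(df, dplyr::across(dplyr::where(is.numeric), ~ format(.x, digits = 15, scientific = FALSE, trim = TRUE)))
  }
  readr::write_tsv(fmt(x$cells), paths[1], progress = FALSE)
  readr::write_tsv(fmt(x$cores), paths[2], progress = FALSE)
  readr::write_tsv(fmt(x$patients), paths[3], progress = FALSE)
  invisible(paths)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  cohort(
    cells = read_cell_table(file.path(dir, "cells.tsv"), quiet = TRUE),
    cores = read_core_table(file.path(dir, "cores.tsv")),
    patients = read_patient_table(file.path(dir, "patients.tsv"))
  )
}
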