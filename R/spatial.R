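# Radius-based cell-cell interaction metrics. Two cells are "in close contact"
# when their Euclidean distance is at most the query radius (closed ball;
# default 20 um). Neighbor search uses uniform grid hashing with bucket size
# equal to the radius, so only the 3x3 neighborhood of a cell's bucket needs
# scanning; results are exactly those of the O(n^2) scan.

grid_candidates <- function(src, tgt, radius_um) {
  # ordered candidate pairs (source row, target row) whose buckets are within
  # one step; includes identical positions
  offsets <- tidyr::expand_grid(dx = -1:1, dy = -1:1)
  s <- tibble(si = seq_len(nrow(src)), x = src$x_um, y = src$y_um,
              gx = floor(src$x_um / radius_um), gy = floor(src$y_um / radius_um))
  t <- tibble(ti = seq_len(nrow(tgt)), tx = tgt$x_um, ty = tgt$y_um,
              gx = floor(tgt$x_um / radius_um), gy = floor(tgt$y_um / radius_um))
  purrr::pmap(offsets, function(dx, dy) {
    dplyr::inner_join(dplyr::mutate(s, gx = .data$gx + dx, gy = .data$gy + dy),
                      t, by = c("gx", "gy"), relationship = "many-to-many")
  }) |>
    dplyr::bind_rows() |>
    dplyr::filter((.data$x - .data$tx)^2 + (.data$y - .data$ty)^2 <= radius_um^2)
}

#' Radius neighbor graph
#'
#' All unordered pairs of cells whose Euclidean distance is at most
#' `radius_um` (closed ball: a pair exactly at the radius is adjacent).
#'
#' @param cells Cell tibble with `x_um`, `y_um`.
#' @param radius_um Positive contact radius in micrometers.
#' @return A tibble of edges `i`, `j` (row indices into `cells`, `i < j`),
#'   sorted.
#' @export
neighbor_graph <- function(cells, radius_um = 20) {
  stopifnot(radius_um > 0)
  if (nrow(cells) < 2) return(tibble(i = integer(), j = integer()))
  pairs <- grid_candidates(cells, cells, radius_um) |>
    dplyr::filter(.data$si < .data$ti)
  tibble(i = pairs$si, j = pairs$ti) |> dplyr::arrange(.data$i, .data$j)
}

#' Spatial interaction query
#'
#' @param source,target Population predicates (character vector of marker
#'   columns or predicate function), see [population_definitions()].
#' @param radius_um Contact radius in micrometers (closed ball).
#' @param exclude_self Whether a cell matching both predicates is excluded
#'   from its own neighbor count (default `TRUE`; only relevant when the
#'   predicates overlap).
#' @return A list of class `timephen_query`.
#' @export
neighbor_query <- function(source, target, radius_um = 20, exclude_self = TRUE) {
  stopifnot(radius_um > 0)
  structure(list(source = source, target = target, radius_um = radius_um,
                 exclude_self = exclude_self), class = "timephen_query")
}

#' Mean neighbor count for a source/target population pair
#'
#' For every source cell, the number of target cells within the query radius;
#' summarized as the mean over source cells. With no source cells the mean is
#' missing (`NA`), never 0; with source cells but no targets in range it is 0.
#'
#' @param cells Cell tibble (one core).
#' @param query A [neighbor_query()].
#' @param core_id Optional identifier stamped into the result.
#' @return A one-row tibble: `core_id`, `source`, `target`, `radius_um`,
#'   `n_source`, `mean_neighbors`, `sd_neighbors`, and a `counts` list-column
#'   with the per-source-cell counts.
#' @export
mean_neighbor_count <- function(cells, query, core_id = NA_character_) {
  stopifnot(inherits(query, "timephen_query"))
  smask <- population_mask(cells, query$source)
  tmask <- population_mask(cells, query$target)
  src <- cells[smask, c("x_um", "y_um")]
  tgt <- cells[tmask, c("x_um", "y_um")]
  label <- function(p) if (is.character(p)) paste(p, collapse = "+") else "custom"
  if (nrow(src) == 0) {
    return(tibble(core_id = core_id, source = label(query$source),
                  target = label(query$target), radius_um = query$radius_um,
                  n_source = 0L, mean_neighbors = NA_real_,
                  sd_neighbors = NA_real_, counts = list(numeric(0))))
  }
  counts <- rep(0, nrow(src))
  if (nrow(tgt) > 0) {
    pairs <- grid_candidates(src, tgt, query$radius_um)
    tab <- table(pairs$si)
    counts[as.integer(names(tab))] <- as.integer(tab)
    if (query$exclude_self) {
      # a cell matching both predicates sits at distance 0 from itself and was
      # counted once in the candidate pairs; remove that self-match
      both <- which(smask & tmask)
      counts[match(both, which(smask))] <- counts[match(both, which(smask))] - 1
    }
  }
  tibble(core_id = core_id, source = label(query$source),
         target = label(query$target), radius_um = query$radius_um,
         n_source = nrow(src), mean_neighbors = mean(counts),
         sd_neighbors = if (length(counts) > 1) sd(counts) else NA_real_,
         counts = list(counts))
}

#' Pairwise mean-neighbor matrix
#'
#' `M[a, b]` is the mean number of b-cells within the radius of each a-cell
#' (self excluded on the diagonal). Not symmetric in general — normalization
#' differs by source population — but edge counts are conserved:
#' `M[a, b] * n_a == M[b, a] * n_b` for `a != b`.
#'
#' @param cells Cell tibble (one core).
#' @param populations Named list of population predicates, by default
#'   [population_definitions()].
#' @param radius_um Contact radius in micrometers.
#' @return A list: `matrix` (mean counts; `NA` where the source population is
#'   empty), `n` (population sizes), `results` (tidy per-pair tibble).
#' @export
interaction_matrix <- function(cells, populations = population_definitions(),
                               radius_um = 20) {
  res <- tidyr::expand_grid(a = names(populations), b = names(populations)) |>
    purrr::pmap(function(a, b) {
      r <- mean_neighbor_count(cells, neighbor_query(populations[[a]],
                                                     populations[[b]],
                                                     radius_um = radius_um))
      dplyr::mutate(r, source = a, target = b)
    }) |> dplyr::bind_rows()
  k <- length(populations)
  m <- matrix(res$mean_neighbors, nrow = k, byrow = TRUE,
              dimnames = list(names(populations), names(populations)))
  n <- vapply(populations, function(p) sum(population_mask(cells, p)), integer(1))
  list(matrix = m, n = n, results = dplyr::select(res, -"counts"))
}

#' Figure-style spatial interaction panel for a cohort
#'
#' Computes, per core, the standard interaction read-outs: tumor-tumor contact
#' (CK vs CK), CD8 spatial clustering (CD8 vs CD8, self excluded),
#' CD8+PD-1+ vs CK+PD-L1+, CD8+PD-1+ vs CD68+PD-L1+, and CD8 vs CD68 / FOXP3 /
#' CK.
#'
#' @param x A `timephen_cohort`.
#' @param radius_um Contact radius in micrometers.
#' @return A tibble, one row per core x query.
#' @export
spatial_panel <- function(x, radius_um = 20) {
  pops <- population_definitions()
  queries <- list(
    tumor_tumor   = neighbor_query(pops$ck, pops$ck, radius_um),
    cd8_cd8       = neighbor_query(pops$cd8, pops$cd8, radius_um),
    cd8pd1_ckpdl1 = neighbor_query(pops$cd8_pd1, pops$ck_pdl1, radius_um),
    cd8pd1_cd68pdl1 = neighbor_query(pops$cd8_pd1, pops$cd68_pdl1, radius_um),
    cd8_cd68      = neighbor_query(pops$cd8, pops$cd68, radius_um),
    cd8_foxp3     = neighbor_query(pops$cd8, pops$foxp3, radius_um),
    cd8_ck        = neighbor_query(pops$cd8, pops$ck, radius_um)
  )
  purrr::map(x$cores$core_id, function(cid) {
    cells <- x$cells[x$cells$core_id == cid, ]
    purrr::imap(queries, function(q, nm) {
      dplyr::mutate(mean_neighbor_count(cells, q, core_id = cid), query = nm,
                    .before = 1)
    }) |> dplyr::bind_rows()
  }) |>
    dplyr::bind_rows() |>
    dplyr::select(-"counts")
}
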