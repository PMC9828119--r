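# Immune-phenotype discovery: z-scaling, Ward hierarchical clustering,
# bootstrap Jaccard stability, rule-based semantic naming, and a silhouette
# criterion for the number of clusters.

#' Column-wise z-scaling
#'
#' Centers each column to zero mean and scales to unit variance using the
#' population standard deviation (divisor n). Zero-variance columns are mapped
#' to all-zeros with a warning so they carry no weight in the distance.
#'
#' @param x A numeric matrix, data frame, or feature tibble from
#'   [build_feature_matrix()] (a `core_id` column is carried through).
#' @return Same shape as the input with scaled numeric columns.
#' @export
scale_features <- function(x) {
  id <- NULL
  if (is.data.frame(x) && "core_id" %in% names(x)) {
    id <- x$core_id
    x <- x[, setdiff(names(x), "core_id")]
  }
  m <- as.matrix(x)
  stopifnot(nrow(m) >= 2, is.numeric(m))
  mu <- colMeans(m)
  sdev <- sqrt(colMeans(sweep(m, 2, mu)^2))
  zero_var <- sdev == 0
  if (any(zero_var)) {
    rlang::warn(paste0("scale_features: ", sum(zero_var),
                       " zero-variance column(s) set to zero."))
    sdev[zero_var] <- 1
  }
  scaled <- sweep(sweep(m, 2, mu), 2, sdev, "/")
  scaled[, zero_var] <- 0
  out <- as_tibble(as.data.frame(scaled))
  if (!is.null(id)) out <- dplyr::bind_cols(tibble(core_id = id), out)
  out
}

as_feature_matrix <- function(x) {
  id <- NULL
  if (is.data.frame(x) && "core_id" %in% names(x)) {
    id <- x$core_id
    x <- x[, setdiff(names(x), "core_id")]
  }
  m <- as.matrix(x)
  if (is.null(id)) id <- rownames(m) %||% as.character(seq_len(nrow(m)))
  rownames(m) <- id
  m
}

#' Agglomerative clustering of core profiles
#'
#' Ward-linkage (`ward.D2`) agglomerative clustering on Euclidean distances,
#' cut into `k` groups. Cluster indices are relabelled by decreasing cluster
#' size so they are stable under row permutation.
#'
#' @param scaled Scaled feature table ([scale_features()] output) or matrix;
#'   a `core_id` column is used for the assignment ids.
#' @param k Number of clusters, `2 <= k <=` number of rows.
#' @return A list of class `timephen_clustering`: `assignments` (tibble of
#'   `core_id`, `cluster_index`), `tree` (hclust), `k`, `sizes`.
#' @export
hierarchical_cluster <- function(scaled, k) {
  m <- as_feature_matrix(scaled)
  if (k > nrow(m)) rlang::abort("hierarchical_cluster: k exceeds number of rows.")
  stopifnot(k >= 2)
  tree <- hclust(dist(m, method = "euclidean"), method = "ward.D2")
  raw <- cutree(tree, k = k)
  # relabel 1..k by decreasing size (ties: by smallest original row index)
  size <- table(raw)
  first_row <- tapply(seq_along(raw), raw, min)
  ord <- order(-as.integer(size), as.integer(first_row))
  relabel <- integer(k)
  relabel[as.integer(names(size))[ord]] <- seq_len(k)
  idx <- relabel[raw]
  structure(list(
    assignments = tibble(core_id = rownames(m), cluster_index = idx),
    tree = tree, k = k,
    sizes = as.integer(table(factor(idx, levels = seq_len(k))))
  ), class = "timephen_clustering")
}

#' @export
print.timephen_clustering <- function(x, ...) {
  cat("<timephen_clustering> k =", x$k, "; sizes:", paste(x$sizes, collapse = ", "), "\n")
  invisible(x)
}

jaccard_sets <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0) return(0)
  length(intersect(a, b)) / u
}

#' Bootstrap Jaccard cluster stability
#'
#' For each of `B` bootstrap resamples of the rows (with replacement), the
#' resample is re-clustered and every original cluster is matched to the
#' bootstrap cluster maximizing the Jaccard coefficient
#' `|A n B| / |A u B|`, computed over the set of distinct resampled rows.
#' An original cluster with no member in a resample scores 0 for that
#' replicate. The mean over replicates, per original cluster, is the stability
#' estimate; values above 0.5 are conventionally read as fair robustness.
#'
#' @param scaled Scaled feature table or matrix.
#' @param k Number of clusters.
#' @param B Number of bootstrap replicates.
#' @param seed Optional integer seed.
#' @return A tibble with `cluster_index`, `mean_jaccard`, `n_boot`.
#' @export
bootstrap_jaccard <- function(scaled, k, B = 100, seed = NULL) {
  stopifnot(B >= 1)
  if (!is.null(seed)) set.seed(seed)
  m <- as_feature_matrix(scaled)
  n <- nrow(m)
  orig <- hierarchical_cluster(m, k)
  orig_sets <- split(seq_len(n), orig$assignments$cluster_index)
  jac <- matrix(0, B, k)
  for (b in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    sub <- m[idx, , drop = FALSE]
    rownames(sub) <- as.character(seq_len(n))
    boot <- hierarchical_cluster(sub, k)
    boot_sets <- lapply(split(seq_len(n), boot$assignments$cluster_index),
                        function(rows) unique(idx[rows]))
    present <- unique(idx)
    for (j in seq_len(k)) {
      a <- intersect(orig_sets[[j]], present)
      if (length(a) == 0) next  # cluster absent from the resample: 0
      jac[b, j] <- max(vapply(boot_sets, jaccard_sets, numeric(1), a = a))
    }
  }
  tibble(cluster_index = seq_len(k), mean_jaccard = colMeans(jac), n_boot = B)
}

#' Semantic naming of immune clusters
#'
#' Applies the naming rules in order on the per-cluster OMD table:
#' TIL-rich is the cluster with the highest CD8 OMD; immune-exclusion the
#' highest CK+PD-L1+ OMD among the rest; macrophage-rich the highest CD68 OMD
#' among the rest; FOXP3-rich the highest FOXP3 OMD among the rest; the
#' remainder is immune-desert provided it also has the lowest total immune OMD
#' (CD8 + CD68 + FOXP3) of all clusters, otherwise it stays `"unnamed"` with a
#' warning. Ties are broken toward the larger cluster (logged via warning).
#' With k < 5, rules are applied until clusters run out (partial naming).
#'
#' @param omd Per-cluster OMD table from [cluster_omd_table()].
#' @return The `omd` tibble with a `semantic_name` column.
#' @export
name_clusters <- function(omd) {
  k <- nrow(omd)
  name <- rep("unnamed", k)
  naming_vars <- c("cd8", "ck_pdl1", "cd68", "foxp3")
  degenerate <- all(vapply(c(naming_vars, "total_immune"),
                           function(v) length(unique(omd[[v]])) == 1, logical(1)))
  if (degenerate) {
    rlang::warn("name_clusters: no variation in OMDs across clusters; all unnamed.")
    omd$semantic_name <- name
    return(omd)
  }
  rules <- c(til_rich = "cd8", immune_exclusion = "ck_pdl1",
             macrophage_rich = "cd68", foxp3_rich = "foxp3")
  remaining <- seq_len(k)
  for (r in seq_along(rules)) {
    if (length(remaining) <= 1) break
    v <- omd[[rules[r]]][remaining]
    top <- which(v == max(v))
    if (length(top) > 1) {
      rlang::warn(paste0("name_clusters: tie on ", rules[r], "; larger cluster wins."))
      top <- top[which.max(omd$n_cores[remaining][top])]
    }
    pick <- remaining[top]
    name[pick] <- names(rules)[r]
    remaining <- setdiff(remaining, pick)
  }
  if (length(remaining) == 1) {
    if (omd$total_immune[remaining] <= min(omd$total_immune)) {
      name[remaining] <- "immune_desert"
    } else {
      rlang::warn("name_clusters: remainder cluster lacks the minimal total immune OMD; left unnamed.")
    }
  }
  omd$semantic_name <- name
  omd
}

#' Choose the number of clusters by mean silhouette
#'
#' Evaluates each k in `k_range` by the mean silhouette width of the Ward
#' partition (primary criterion) and reports the mean bootstrap Jaccard over
#' clusters as a secondary diagnostic. When the best mean silhouette is below
#' 0.25 the diagnostics flag "no support for k > 1" (conventional weak-
#' structure threshold).
#'
#' @param scaled Scaled feature table or matrix.
#' @param k_range Integer vector of candidate k (each in 2..rows-1).
#' @param B Bootstrap replicates per k for the secondary diagnostic (0 to
#'   skip).
#' @param seed Optional seed for the bootstrap diagnostic.
#' @return A list: `k` (the silhouette argmax), `diagnostics` (tibble of k,
#'   mean_silhouette, mean_jaccard), `support` flag.
#' @export
choose_k <- function(scaled, k_range = 2:8, B = 20, seed = NULL) {
  m <- as_feature_matrix(scaled)
  stopifnot(all(k_range >= 2), all(k_range <= nrow(m) - 1))
  d <- dist(m, method = "euclidean")
  diag <- purrr::map(k_range, function(k) {
    cl <- hierarchical_cluster(m, k)
    sil <- cluster::silhouette(cl$assignments$cluster_index, d)
    mj <- if (B > 0) {
      mean(bootstrap_jaccard(m, k, B = B, seed = seed)$mean_jaccard)
    } else NA_real_
    tibble(k = k, mean_silhouette = mean(sil[, "sil_width"]), mean_jaccard = mj)
  }) |> dplyr::bind_rows()
  best <- diag$k[which.max(diag$mean_silhouette)]
  support <- max(diag$mean_silhouette) >= 0.25
  list(k = best, diagnostics = diag,
       support = if (support) "ok" else "no support for k > 1")
}

#' Adjusted Rand index between two labelings
#'
#' Thin wrapper over [mclust::adjustedRandIndex()] for comparing a recovered
#' partition with planted ground truth.
#'
#' @param a,b Label vectors of equal length.
#' @return The ARI (1 = identical partitions, ~0 = chance).
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  mclust::adjustedRandIndex(a, b)
}

#' Full phenotype-discovery pipeline for one cohort
#'
#' Builds the density feature matrix, z-scales it, clusters with Ward linkage
#' at `k`, estimates bootstrap Jaccard stability, computes per-cluster OMDs and
#' attaches semantic names.
#'
#' @param x A `timephen_cohort`.
#' @param k Number of clusters (pinned to 5 in the reference pipeline).
#' @param B Bootstrap replicates for stability.
#' @param seed Optional seed for the stability bootstrap.
#' @return A list of class `timephen_phenotypes`: `assignments` (core_id,
#'   cluster_index, semantic_name, jaccard_stability), `omd` (named OMD table),
#'   `stability`, `clustering`, `profiles`.
#' @export
phenotype_cohort <- function(x, k = 5, B = 100, seed = NULL) {
  features <- build_feature_matrix(x, include_fractions = FALSE)
  scaled <- scale_features(features)
  cl <- hierarchical_cluster(scaled, k)
  stab <- bootstrap_jaccard(scaled, k, B = B, seed = seed)
  profiles <- core_profiles(x)
  omd <- name_clusters(cluster_omd_table(profiles, cl$assignments))
  assignments <- cl$assignments |>
    dplyr::left_join(omd[, c("cluster_index", "semantic_name")], by = "cluster_index") |>
    dplyr::left_join(stab[, c("cluster_index", "mean_jaccard")], by = "cluster_index") |>
    dplyr::rename(jaccard_stability = "mean_jaccard")
  structure(list(assignments = assignments, omd = omd, stability = stab,
                 clustering = cl, profiles = profiles),
            class = "timephen_phenotypes")
}

#' @export
print.timephen_phenotypes <- function(x, ...) {
  cat("<timephen_phenotypes> k =", x$clustering$k, "\n")
  print(dplyr::count(x$assignments, .data$semantic_name))
  invisible(x)
}
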