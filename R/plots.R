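# ggplot2 visualizations for the pipeline's result objects.

#' Plot phenotype-discovery results
#'
#' A scaled-OMD tile plot: clusters (with semantic names and Jaccard
#' stability) against the canonical populations, each column z-scaled across
#' clusters.
#'
#' @param object A `timephen_phenotypes`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot timephen_phenotypes
#' @export
autoplot.timephen_phenotypes <- function(object, ...) {
  g <- glance(object)
  long <- g |>
    dplyr::mutate(cluster = paste0(.data$semantic_name, " (n=", .data$n_cores, ")")) |>
    tidyr::pivot_longer(c("cd8", "cd68", "foxp3", "ck", "ck_pdl1"),
                        names_to = "population", values_to = "omd") |>
    dplyr::group_by(.data$population) |>
    dplyr::mutate(z = as.numeric(scale(.data$omd))) |>
    dplyr::ungroup()
  ggplot(long, aes(x = .data$population, y = .data$cluster, fill = .data$z)) +
    geom_tile() +
    scale_fill_gradient2(low = "#2166ac", mid = "white", high = "#b2182b") +
    labs(x = NULL, y = NULL, fill = "scaled OMD",
         title = "Immune phenotypes: per-cluster overall median densities") +
    theme_minimal()
}

#' Plot a ROC curve
#'
#' @param object A `timephen_roc`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot timephen_roc
#' @export
autoplot.timephen_roc <- function(object, ...) {
  ggplot(object$roc, aes(x = 1 - .data$specificity, y = .data$sensitivity)) +
    geom_step(direction = "hv") +
    geom_abline(linetype = "dashed", color = "grey60") +
    coord_equal() +
    labs(x = "1 - specificity", y = "Sensitivity",
         title = sprintf("ROC curve (AUC = %.3f)", object$auc)) +
    theme_minimal()
}

#' Plot Kaplan-Meier curves
#'
#' @param object A `timephen_km`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot timephen_km
#' @export
autoplot.timephen_km <- function(object, ...) {
  curves <- object$curves |>
    dplyr::group_by(.data$group) |>
    dplyr::group_modify(~ dplyr::bind_rows(
      tibble(time = 0, n_risk = max(.x$n_risk), n_event = 0, survival = 1), .x
    )) |>
    dplyr::ungroup()
  p <- ggplot(curves, aes(x = .data$time, y = .data$survival, color = .data$group)) +
    geom_step(direction = "hv") +
    scale_y_continuous(limits = c(0, 1)) +
    labs(x = "Months", y = "Relapse-free survival", color = NULL,
         title = "Kaplan-Meier relapse-free survival") +
    theme_minimal()
  if (!is.na(object$logrank_p)) {
    p <- p + labs(subtitle = sprintf("log-rank p = %.3g", object$logrank_p))
  }
  p
}

#' Plot per-core spatial interaction summaries by phenotype
#'
#' Boxplots of mean neighbor counts per core, split by query and phenotype.
#'
#' @param panel Output of [spatial_panel()].
#' @param assignments Tibble with `core_id`, `semantic_name`.
#' @return A ggplot.
#' @export
plot_spatial_panel <- function(panel, assignments) {
  df <- dplyr::inner_join(panel, assignments[, c("core_id", "semantic_name")],
                          by = "core_id")
  ggplot(df, aes(x = .data$semantic_name, y = .data$mean_neighbors,
                 fill = .data$semantic_name)) +
    geom_boxplot(outlier.size = 0.5, show.legend = FALSE) +
    facet_wrap(~query, scales = "free_y") +
    labs(x = NULL, y = "Mean neighbors per source cell") +
    theme_minimal() +
    theme(axis.text.x = element_text(angle = 45, hjust = 1))
}
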