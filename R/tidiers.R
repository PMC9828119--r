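# broom-style tidy()/glance() methods for the package's fitted objects.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @rdname fit_logistic
#' @param x A `timephen_logit`.
#' @param ... Unused.
#' @method tidy timephen_logit
#' @export
tidy.timephen_logit <- function(x, ...) {
  se <- sqrt(diag(x$vcov))
  z <- x$coefficients / se
  tibble(term = names(x$coefficients), estimate = unname(x$coefficients),
         std.error = se, statistic = unname(z),
         p.value = 2 * stats::pnorm(-abs(unname(z))))
}

#' @rdname fit_logistic
#' @method glance timephen_logit
#' @export
glance.timephen_logit <- function(x, ...) {
  k <- length(x$coefficients)
  tibble(nobs = x$n, logLik = x$loglik, AIC = -2 * x$loglik + 2 * k,
         converged = x$converged, ridge = x$ridge_used)
}

#' @rdname phenotype_cohort
#' @param x A `timephen_phenotypes`.
#' @param ... Unused.
#' @method tidy timephen_phenotypes
#' @export
tidy.timephen_phenotypes <- function(x, ...) x$assignments

#' @rdname phenotype_cohort
#' @method glance timephen_phenotypes
#' @export
glance.timephen_phenotypes <- function(x, ...) {
  x$omd |>
    dplyr::left_join(x$stability, by = "cluster_index") |>
    dplyr::select("cluster_index", "semantic_name", "n_cores", "mean_jaccard",
                  "cd8", "cd68", "foxp3", "ck", "ck_pdl1", "total_immune")
}

#' @rdname exhaustive_search
#' @param x A `timephen_search`.
#' @param ... Unused.
#' @method tidy timephen_search
#' @export
tidy.timephen_search <- function(x, ...) dplyr::arrange(x$results, .data$cv_error)

#' @rdname exhaustive_search
#' @method glance timephen_search
#' @export
glance.timephen_search <- function(x, ...) {
  tibble(n_subsets = nrow(x$results),
         best_features = paste(x$best_features, collapse = "+"),
         best_cv_error = x$best_error)
}

#' @rdname roc_auc
#' @param x A `timephen_roc`.
#' @param ... Unused.
#' @method tidy timephen_roc
#' @export
tidy.timephen_roc <- function(x, ...) x$roc

#' @rdname roc_auc
#' @method glance timephen_roc
#' @export
glance.timephen_roc <- function(x, ...) tibble(auc = x$auc)

#' @rdname km_estimate
#' @param x A `timephen_km`.
#' @param ... Unused.
#' @method tidy timephen_km
#' @export
tidy.timephen_km <- function(x, ...) x$curves

#' @rdname km_estimate
#' @method glance timephen_km
#' @export
glance.timephen_km <- function(x, ...) {
  tibble(n_groups = dplyr::n_distinct(x$curves$group),
         logrank_chisq = x$logrank_chisq, logrank_p = x$logrank_p)
}

#' @rdname fit_cart
#' @param x A `timephen_tree`.
#' @param ... Unused.
#' @method tidy timephen_tree
#' @export
tidy.timephen_tree <- function(x, ...) {
  if (is.null(x$fit)) {
    return(tibble(node = 1L, variable = "<leaf>", n = NA_integer_,
                  is_leaf = TRUE, predicted_class = x$constant_class))
  }
  fr <- x$fit$frame
  ylev <- attr(x$fit, "ylevels")
  tibble(node = as.integer(rownames(fr)), variable = as.character(fr$var),
         n = fr$n, is_leaf = fr$var == "<leaf>",
         predicted_class = ylev[fr$yval])
}
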