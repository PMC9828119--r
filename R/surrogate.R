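# CART surrogate: maps intra-tumoral single-marker densities (the quantities a
# pathologist can approximate on whole-slide single-marker IHC) to the immune
# phenotypes discovered by the multiplex pipeline, via recursive partitioning.

#' Intra-tumoral marker features for the surrogate tree
#'
#' Tumor-scope densities of CD8, CD68, FOXP3 and of PD-L1+ tumor cells
#' (CK+PD-L1+) per core — the four markers available to single-marker IHC.
#'
#' @param x A `timephen_cohort`.
#' @return A tibble: `core_id`, `cd8`, `cd68`, `foxp3`, `pdl1`.
#' @export
intratumoral_features <- function(x) {
  build_feature_matrix(x, include_fractions = FALSE) |>
    dplyr::select("core_id", cd8 = "d_cd8_tumor", cd68 = "d_cd68_tumor",
                  foxp3 = "d_foxp3_tumor", pdl1 = "d_ck_pdl1_tumor")
}

#' Fit a CART surrogate tree
#'
#' Greedy recursive partitioning (Gini impurity) of phenotype labels on
#' intra-tumoral marker densities, with rpart-style controls: minimum leaf
#' size 5, maximum depth 5, growth threshold `cp` = 0.01, followed by
#' cost-complexity pruning at the 1-SE cross-validated complexity (the
#' standard rpart workflow; on label-free noise this collapses the tree to a
#' stump). The internal cross-validation folds are drawn from a fixed local
#' seed, so the fit is deterministic given the data. A single-class input
#' yields a constant one-leaf tree with a warning.
#'
#' @param features Tibble of numeric features (a `core_id` column is ignored
#'   as a predictor).
#' @param labels Phenotype labels aligned with `features` rows.
#' @param minbucket,maxdepth,cp Control parameters passed to
#'   [rpart::rpart.control()].
#' @param prune Apply 1-SE cost-complexity pruning after growth (default
#'   `TRUE`).
#' @return An object of class `timephen_tree` wrapping the `rpart` fit.
#' @export
fit_cart <- function(features, labels, minbucket = 5, maxdepth = 5, cp = 0.01,
                     prune = TRUE) {
  df <- as.data.frame(features[, setdiff(names(features), "core_id")])
  df$.label <- factor(labels)
  control <- list(minbucket = minbucket, maxdepth = maxdepth, cp = cp)
  if (nlevels(df$.label) < 2) {
    rlang::warn("fit_cart: single-class input; returning a one-leaf tree.")
    return(structure(list(fit = NULL, constant_class = levels(df$.label),
                          features = setdiff(names(features), "core_id"),
                          control = control, precision_mode = "resubstitution"),
                     class = "timephen_tree"))
  }
  fit <- withr::with_seed(20203011, {
    grown <- rpart::rpart(.label ~ ., data = df, method = "class",
                          control = rpart::rpart.control(minbucket = minbucket,
                                                         maxdepth = maxdepth,
                                                         cp = cp, xval = 10))
    if (prune && nrow(grown$cptable) > 1) {
      cpt <- grown$cptable
      min_x <- min(cpt[, "xerror"])
      thresh <- min_x + cpt[which.min(cpt[, "xerror"]), "xstd"]
      best_cp <- cpt[which(cpt[, "xerror"] <= thresh)[1], "CP"]
      rpart::prune(grown, cp = best_cp)
    } else {
      grown
    }
  })
  structure(list(fit = fit, constant_class = NULL,
                 features = setdiff(names(features), "core_id"),
                 control = control, precision_mode = "resubstitution"),
            class = "timephen_tree")
}

#' @rdname fit_cart
#' @param ... Passed on to [fit_cart()].
#' @details `simplified_tree()` restricts the features to intra-tumoral CD8
#'   and PD-L1 — the two-marker panel — before fitting.
#' @export
simplified_tree <- function(features, labels, ...) {
  keep <- intersect(names(features), c("core_id", "cd8", "pdl1"))
  fit_cart(features[, keep], labels, ...)
}

#' @export
predict.timephen_tree <- function(object, newdata, ...) {
  df <- as.data.frame(newdata[, object$features, drop = FALSE])
  if (is.null(object$fit)) {
    return(factor(rep(object$constant_class, nrow(df))))
  }
  if (nrow(object$fit$frame) == 1) {
    # one-leaf tree: constant prediction
    return(factor(rep(object$fit$frame$yval, nrow(df)),
                  levels = seq_along(attr(object$fit, "ylevels")),
                  labels = attr(object$fit, "ylevels")))
  }
  predict(object$fit, df, type = "class")
}

n_leaves <- function(x) {
  if (is.null(x$fit)) 1L else sum(x$fit$frame$var == "<leaf>")
}

#' @export
print.timephen_tree <- function(x, ...) {
  cat("<timephen_tree> features:", paste(x$features, collapse = ", "),
      "| leaves:", n_leaves(x), "\n")
  if (!is.null(x$fit)) print(x$fit) else cat("constant:", x$constant_class, "\n")
  invisible(x)
}

#' Per-class precision of a surrogate tree
#'
#' For each phenotype class, TP / (TP + FP) of the tree's predictions on the
#' given data (resubstitution on the fitting data unless held-out data are
#' supplied). Classes the tree never predicts have missing precision and are
#' flagged.
#'
#' @param tree A `timephen_tree`.
#' @param features Feature tibble.
#' @param labels True labels.
#' @return A tibble: `class`, `n_true`, `n_predicted`, `precision`, `flag`.
#' @export
per_class_precision <- function(tree, features, labels) {
  pred <- as.character(predict(tree, features))
  truth <- as.character(labels)
  purrr::map(sort(unique(truth)), function(cl) {
    n_pred <- sum(pred == cl)
    tibble(class = cl, n_true = sum(truth == cl), n_predicted = n_pred,
           precision = if (n_pred > 0) sum(pred == cl & truth == cl) / n_pred else NA_real_,
           flag = if (n_pred > 0) "ok" else "never predicted")
  }) |> dplyr::bind_rows()
}
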