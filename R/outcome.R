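# Patient-level aggregation and the clinical-outcome layer: reference vs
# immune-optimized logistic models, exhaustive feature-subset search with
# repeated stratified cross-validation, ROC/Youden stratification, bootstrap
# model comparison, Kaplan-Meier curves and enrichment tests.

#' Aggregate core phenotypes to patients
#'
#' Computes, per patient, carriage (">= 1 core of that phenotype") and purity
#' ("all analyzed cores share that phenotype"; for single-core patients purity
#' equals carriage) for every semantic phenotype, and joins the clinical
#' covariates. Patients with no assigned cores are excluded with a warning.
#'
#' @param assignments Tibble with `core_id`, `semantic_name` (e.g. from
#'   [phenotype_cohort()]).
#' @param x The `timephen_cohort` providing core-to-patient mapping and
#'   clinical data.
#' @return A patient-features tibble: clinical covariates, `carriage_*` and
#'   `purity_*` logicals, `n_cores`, `relapse`, `followup_months`.
#' @export
aggregate_patients <- function(assignments, x) {
  stopifnot(inherits(x, "timephen_cohort"))
  joined <- dplyr::inner_join(assignments[, c("core_id", "semantic_name")],
                              x$cores[, c("core_id", "patient_id")], by = "core_id")
  phenos <- union(ARCHETYPE_NAMES, unique(joined$semantic_name))
  per_patient <- joined |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(n_cores = dplyr::n(),
                     phenotypes = list(.data$semantic_name), .groups = "drop")
  for (p in phenos) {
    per_patient[[paste0("carriage_", p)]] <-
      purrr::map_lgl(per_patient$phenotypes, ~ p %in% .x)
    per_patient[[paste0("purity_", p)]] <-
      purrr::map_lgl(per_patient$phenotypes, ~ all(.x == p))
  }
  per_patient$phenotypes <- NULL
  missing <- setdiff(x$patients$patient_id, per_patient$patient_id)
  if (length(missing) > 0) {
    rlang::warn(paste0("aggregate_patients: ", length(missing),
                       " patient(s) with no assigned cores excluded."))
  }
  dplyr::inner_join(x$patients, per_patient, by = "patient_id")
}

#' Exclude patients with insufficient follow-up
#'
#' Removes non-relapsed patients followed for less than `min_months`; relapsed
#' patients are always retained (their event, not their censoring time, is the
#' information). The exclusion log is attached as attribute `exclusions`.
#'
#' @param patients Patient tibble with `relapse`, `followup_months`.
#' @param min_months Minimum follow-up for non-relapsers (default 36).
#' @return The filtered tibble with attribute `exclusions`.
#' @export
filter_followup <- function(patients, min_months = 36) {
  drop <- !patients$relapse & patients$followup_months < min_months
  out <- patients[!drop, ]
  attr(out, "exclusions") <- tibble(
    patient_id = patients$patient_id[drop],
    followup_months = patients$followup_months[drop],
    reason = "non-relapse follow-up below minimum"
  )
  out
}

#' Encode clinical covariates numerically
#'
#' FIGO stage as an ordered integer (IA = 0, IB = 1, II = 2), grade as a G2
#' indicator, LVSI as 0/1. Carriage/purity logicals need no encoding (they
#' enter model matrices as 0/1 directly).
#'
#' @param patients Patient tibble.
#' @return The tibble with added `figo_num`, `grade_num`, `lvsi_num` columns.
#' @export
encode_covariates <- function(patients) {
  dplyr::mutate(patients,
    figo_num = c(IA = 0, IB = 1, II = 2)[.data$figo_stage],
    grade_num = as.numeric(.data$grade == "G2"),
    lvsi_num = as.numeric(.data$lvsi)
  )
}

#' Logistic regression by iteratively reweighted least squares
#'
#' Maximum-likelihood logistic fit with an intercept, converging when the
#' largest coefficient change falls below 1e-8 (at most 100 iterations).
#' Quasi-separation (non-convergence or runaway coefficients) is handled by
#' refitting with a tiny ridge penalty (1e-6) and flagging the fit.
#'
#' @param data Tibble of covariates (numeric or logical columns).
#' @param outcome Name of the binary outcome column (logical or 0/1).
#' @param features Character vector of covariate columns; empty fits
#'   intercept-only.
#' @param ridge Ridge penalty added to the normal equations (default 0).
#' @return An object of class `timephen_logit` with `coefficients`, `vcov`,
#'   `converged`, `ridge_used`, `loglik`, `n`.
#' @export
fit_logistic <- function(data, outcome, features, ridge = 0) {
  y <- as.numeric(data[[outcome]])
  stopifnot(all(y %in% c(0, 1)))
  if (length(unique(y)) < 2) rlang::abort("fit_logistic: outcome has a single class.")
  X <- cbind(`(Intercept)` = 1,
             as.matrix(dplyr::mutate(data[, features, drop = FALSE],
                                     dplyr::across(dplyr::everything(), as.numeric))))
  irls <- function(lambda) {
    beta <- rep(0, ncol(X))
    converged <- FALSE
    singular <- FALSE
    H <- diag(ncol(X))
    for (it in seq_len(100)) {
      eta <- drop(X %*% beta)
      mu <- plogis(eta)
      w <- pmax(mu * (1 - mu), 1e-10)
      z <- eta + (y - mu) / w
      XtW <- t(X * w)
      H <- XtW %*% X + diag(lambda, ncol(X))
      new_beta <- tryCatch(drop(solve(H, XtW %*% z)), error = function(e) NULL)
      if (is.null(new_beta)) { singular <- TRUE; break }
      delta <- max(abs(new_beta - beta))
      beta <- new_beta
      if (delta < 1e-8) { converged <- TRUE; break }
    }
    list(beta = beta, converged = converged, singular = singular, H = H)
  }
  fit <- irls(ridge)
  ridge_used <- ridge
  if (fit$singular || !fit$converged || max(abs(fit$beta)) > 15) {
    # quasi-separation or a (fold-)degenerate design: refit with a tiny ridge,
    # which keeps the normal equations positive definite
    ridge_used <- max(ridge, 1e-6)
    fit <- irls(ridge_used)
    if (ridge == 0) {
      rlang::inform("fit_logistic: quasi-separation detected; refit with ridge 1e-6.")
    }
    if (fit$singular) rlang::abort("fit_logistic: design remains singular under ridge.")
  }
  eta <- drop(X %*% fit$beta)
  structure(list(
    coefficients = setNames(fit$beta, colnames(X)),
    vcov = solve(fit$H),
    converged = fit$converged, ridge_used = ridge_used,
    loglik = sum(y * eta - log1p(exp(eta))),
    n = length(y), outcome = outcome, features = features
  ), class = "timephen_logit")
}

#' @export
predict.timephen_logit <- function(object, newdata, type = c("response", "link"), ...) {
  type <- match.arg(type)
  X <- cbind(1, as.matrix(dplyr::mutate(newdata[, object$features, drop = FALSE],
                                        dplyr::across(dplyr::everything(), as.numeric))))
  eta <- drop(X %*% object$coefficients)
  if (type == "link") eta else plogis(eta)
}

#' @export
print.timephen_logit <- function(x, ...) {
  cat("<timephen_logit> n =", x$n, if (x$ridge_used > 0) " (ridge)" else "", "\n")
  print(round(x$coefficients, 4))
  invisible(x)
}

stratified_folds <- function(y, folds) {
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    fold[idx] <- rep_len(seq_len(folds), length(idx))
  }
  fold
}

cv_misclassification <- function(data, outcome, features, fold_sets) {
  y <- as.numeric(data[[outcome]])
  errs <- purrr::map_dbl(fold_sets, function(fold) {
    wrong <- 0L
    for (f in sort(unique(fold))) {
      train <- data[fold != f, ]
      test <- data[fold == f, ]
      # separation in deliberately weak candidate subsets is routine here;
      # the ridge fallback handles it silently
      m <- suppressMessages(fit_logistic(train, outcome, features))
      pred <- predict(m, test) >= 0.5
      wrong <- wrong + sum(pred != as.logical(y[fold == f]))
    }
    wrong / length(y)
  })
  mean(errs)
}

#' Exhaustive feature-subset selection by repeated cross-validation
#'
#' Fits a logistic model for every non-empty subset of the candidate features
#' and scores each by mean misclassification error (held-out class predicted
#' at probability 0.5) under `repeats` rounds of stratified `folds`-fold
#' cross-validation. Fold assignments are drawn once per repeat and shared by
#' all subsets. The arg-min subset is selected; ties go to fewer features,
#' then lexicographic order. A training fold containing a single outcome class
#' is refolded with a new draw (logged).
#'
#' @param data Patient features tibble (numeric/logical candidate columns).
#' @param outcome Binary outcome column name.
#' @param candidates Character vector of candidate features (at most 20).
#' @param folds,repeats Cross-validation geometry (default 2-fold, 20 times).
#' @param seed Optional integer seed.
#' @return An object of class `timephen_search`: `results` (one row per
#'   subset with `features`, `n_features`, `cv_error`), `best_features`,
#'   `best_error`, `model` (final refit on all data).
#' @export
exhaustive_search <- function(data, outcome, candidates, folds = 2, repeats = 20,
                              seed = NULL) {
  stopifnot(length(candidates) >= 1, length(candidates) <= 20)
  if (!is.null(seed)) set.seed(seed)
  y <- as.numeric(data[[outcome]])
  fold_sets <- purrr::map(seq_len(repeats), function(r) {
    for (try in 1:50) {
      fold <- stratified_folds(y, folds)
      ok <- all(vapply(seq_len(folds), function(f) {
        length(unique(y[fold != f])) == 2
      }, logical(1)))
      if (ok) return(fold)
      rlang::inform("exhaustive_search: degenerate fold; redrawing.")
    }
    rlang::abort("exhaustive_search: could not build two-class folds.")
  })
  subsets <- unlist(lapply(seq_along(candidates), function(sz) {
    combn(candidates, sz, simplify = FALSE)
  }), recursive = FALSE)
  errors <- purrr::map_dbl(subsets, function(fs) {
    cv_misclassification(data, outcome, fs, fold_sets)
  })
  results <- tibble(
    features = purrr::map_chr(subsets, paste, collapse = "+"),
    n_features = lengths(subsets), cv_error = errors
  )
  ord <- order(errors, lengths(subsets), results$features)
  best <- subsets[[ord[1]]]
  structure(list(results = results, best_features = best,
                 best_error = errors[ord[1]],
                 model = fit_logistic(data, outcome, best)),
            class = "timephen_search")
}

#' @export
print.timephen_search <- function(x, ...) {
  cat("<timephen_search>", nrow(x$results), "subsets; best:",
      paste(x$best_features, collapse = " + "),
      sprintf("(CV error %.4f)\n", x$best_error))
  invisible(x)
}

auc_mw <- function(scores, y) {
  # Mann-Whitney U identity with half-credit for ties
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  r <- rank(scores, ties.method = "average")
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve and AUC
#'
#' AUC by the Mann-Whitney U identity (tied scores get half credit) and the
#' ROC operating points at every distinct score threshold (prediction positive
#' when score >= threshold).
#'
#' @param scores Numeric risk scores.
#' @param labels Binary outcomes (logical or 0/1); both classes required.
#' @return A list of class `timephen_roc`: `auc` and `roc` (tibble of
#'   `threshold`, `sensitivity`, `specificity`).
#' @export
roc_auc <- function(scores, labels) {
  y <- as.numeric(labels)
  stopifnot(length(scores) == length(y), all(y %in% c(0, 1)))
  if (length(unique(y)) < 2) rlang::abort("roc_auc: both classes required.")
  thresholds <- c(sort(unique(scores)), Inf)
  pts <- purrr::map(thresholds, function(th) {
    pred <- scores >= th
    tibble(threshold = th,
           sensitivity = sum(pred & y == 1) / sum(y == 1),
           specificity = sum(!pred & y == 0) / sum(y == 0))
  }) |> dplyr::bind_rows()
  structure(list(auc = auc_mw(scores, y), roc = pts), class = "timephen_roc")
}

#' @export
print.timephen_roc <- function(x, ...) {
  cat(sprintf("<timephen_roc> AUC = %.4f (%d operating points)\n",
              x$auc, nrow(x$roc)))
  invisible(x)
}

confusion_metrics <- function(pred, y) {
  tp <- sum(pred & y == 1); fn <- sum(!pred & y == 1)
  fp <- sum(pred & y == 0); tn <- sum(!pred & y == 0)
  tibble(
    tp = tp, fp = fp, fn = fn, tn = tn,
    sensitivity = tp / (tp + fn), specificity = tn / (tn + fp),
    ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_
  )
}

#' Youden-index risk stratification
#'
#' Scans every distinct score as a candidate cut-off (prediction positive when
#' score >= cut-off) and selects the one maximizing the Youden index
#' J = sensitivity + specificity - 1; ties are resolved toward higher
#' specificity. Returns the cut-off together with the confusion metrics of the
#' induced high/low-risk split.
#'
#' @inheritParams roc_auc
#' @return A one-row tibble: `cutoff`, `youden`, `sensitivity`, `specificity`,
#'   `ppv`, `npv`, `tp`, `fp`, `fn`, `tn`.
#' @export
youden_stratify <- function(scores, labels) {
  y <- as.numeric(labels)
  stopifnot(length(scores) == length(y), all(y %in% c(0, 1)))
  if (length(unique(y)) < 2) rlang::abort("youden_stratify: both classes required.")
  cand <- sort(unique(scores))
  rows <- purrr::map(cand, function(th) {
    cm <- confusion_metrics(scores >= th, y)
    dplyr::mutate(cm, cutoff = th, youden = .data$sensitivity + .data$specificity - 1)
  }) |> dplyr::bind_rows()
  best <- rows |>
    dplyr::arrange(dplyr::desc(.data$youden), dplyr::desc(.data$specificity)) |>
    dplyr::slice(1)
  dplyr::select(best, "cutoff", "youden", "sensitivity", "specificity",
                "ppv", "npv", "tp", "fp", "fn", "tn")
}

#' Predictive values from sensitivity, specificity and prevalence
#'
#' Bayes-theorem conversion:
#' `PPV = sens*pi / (sens*pi + (1-spec)*(1-pi))`,
#' `NPV = spec*(1-pi) / (spec*(1-pi) + (1-sens)*pi)`.
#' A zero denominator yields `NA`.
#'
#' @param sensitivity,specificity,prevalence Probabilities in \[0, 1\]
#'   (vectorized).
#' @return A tibble with `ppv` and `npv`.
#' @export
ppv_npv_from_rates <- function(sensitivity, specificity, prevalence) {
  stopifnot(all(c(sensitivity, specificity, prevalence) >= 0),
            all(c(sensitivity, specificity, prevalence) <= 1))
  d1 <- sensitivity * prevalence + (1 - specificity) * (1 - prevalence)
  d2 <- specificity * (1 - prevalence) + (1 - sensitivity) * prevalence
  tibble(ppv = ifelse(d1 > 0, sensitivity * prevalence / d1, NA_real_),
         npv = ifelse(d2 > 0, specificity * (1 - prevalence) / d2, NA_real_))
}

#' Paired bootstrap comparison of two risk models
#'
#' Resamples patients with replacement `B` times (redrawing any replicate that
#' loses an outcome class) and computes both models' AUCs on each replicate.
#' Reports how often model A's AUC strictly exceeds model B's (replicates with
#' exactly equal AUCs count for neither model) and each model's empirical
#' p5/p95 AUC range.
#'
#' @param scores_a,scores_b Aligned risk-score vectors for the two models.
#' @param labels Binary outcomes.
#' @param B Number of bootstrap replicates (default 10,000).
#' @param seed Optional integer seed.
#' @return A list of class `timephen_boot`: `outperform_count`, `tie_count`,
#'   `B`, `auc` (tibble per model: mean, p5, p95).
#' @export
bootstrap_compare <- function(scores_a, scores_b, labels, B = 10000, seed = NULL) {
  y <- as.numeric(labels)
  stopifnot(length(scores_a) == length(y), length(scores_b) == length(y))
  if (!is.null(seed)) set.seed(seed)
  n <- length(y)
  auc_a <- numeric(B); auc_b <- numeric(B)
  for (b in seq_len(B)) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      if (length(unique(y[idx])) == 2) break
    }
    auc_a[b] <- auc_mw(scores_a[idx], y[idx])
    auc_b[b] <- auc_mw(scores_b[idx], y[idx])
  }
  structure(list(
    outperform_count = sum(auc_a > auc_b), tie_count = sum(auc_a == auc_b), B = B,
    auc = tibble(model = c("A", "B"),
                 mean = c(mean(auc_a), mean(auc_b)),
                 p5 = c(quantile(auc_a, 0.05, names = FALSE),
                        quantile(auc_b, 0.05, names = FALSE)),
                 p95 = c(quantile(auc_a, 0.95, names = FALSE),
                         quantile(auc_b, 0.95, names = FALSE))),
    auc_a = auc_a, auc_b = auc_b
  ), class = "timephen_boot")
}

#' @export
print.timephen_boot <- function(x, ...) {
  cat(sprintf("<timephen_boot> A > B in %d / %d replicates (%d ties)\n",
              x$outperform_count, x$B, x$tie_count))
  print(x$auc)
  invisible(x)
}

#' Kaplan-Meier relapse-free survival
#'
#' Product-limit estimates per group via [survival::survfit()], with the
#' two-or-more-group log-rank test from [survival::survdiff()].
#'
#' @param times Follow-up times (months, >= 0).
#' @param events Event indicators (logical or 0/1; relapse = 1).
#' @param groups Optional grouping vector (e.g. high/low risk).
#' @return A list of class `timephen_km`: `curves` (tibble of `group`, `time`,
#'   `n_risk`, `n_event`, `survival`), `logrank_chisq`, `logrank_p` (NA for a
#'   single group), `fit`.
#' @export
km_estimate <- function(times, events, groups = NULL) {
  stopifnot(all(times >= 0))
  ev <- as.numeric(events)
  g <- if (is.null(groups)) factor(rep("all", length(times))) else as.factor(groups)
  if (any(table(g) == 0)) rlang::abort("km_estimate: empty group.")
  df <- data.frame(time = times, event = ev, group = g)
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = df)
  s <- summary(fit, censored = TRUE)
  strata <- if (is.null(s$strata)) rep(levels(g)[1], length(s$time)) else
    sub("^group=", "", as.character(s$strata))
  curves <- tibble(group = strata, time = s$time, n_risk = s$n.risk,
                   n_event = s$n.event, survival = s$surv)
  chisq <- p <- NA_real_
  if (nlevels(g) >= 2) {
    sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = df)
    chisq <- sd$chisq
    p <- stats::pchisq(sd$chisq, df = nlevels(g) - 1, lower.tail = FALSE)
  }
  structure(list(curves = curves, logrank_chisq = chisq, logrank_p = p, fit = fit),
            class = "timephen_km")
}

#' @export
print.timephen_km <- function(x, ...) {
  cat("<timephen_km>", dplyr::n_distinct(x$curves$group), "group(s)")
  if (!is.na(x$logrank_chisq)) {
    cat(sprintf("; log-rank chi-square = %.3f (p = %.4g)", x$logrank_chisq, x$logrank_p))
  }
  cat("\n")
  invisible(x)
}

#' Fisher exact enrichment test
#'
#' Exact hypergeometric test for 2x2 tables; for larger tables the exact
#' network algorithm is attempted first and, if it fails (workspace), a seeded
#' Monte-Carlo estimate is used and flagged in the `method` field.
#'
#' @param tab A non-negative integer contingency table (matrix).
#' @param seed Seed for the Monte-Carlo fallback.
#' @param B Monte-Carlo replicates for the fallback.
#' @return A tibble with `p_value` and `method`.
#' @export
enrichment_test <- function(tab, seed = 1L, B = 1e5) {
  tab <- as.matrix(tab)
  stopifnot(all(tab >= 0), all(tab == round(tab)))
  if (sum(tab) == 0) rlang::abort("enrichment_test: all-zero table.")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    rlang::abort("enrichment_test: table has an all-zero row or column.")
  }
  exact <- tryCatch(fisher.test(tab), error = function(e) NULL)
  if (!is.null(exact)) {
    return(tibble(p_value = exact$p.value, method = "exact"))
  }
  set.seed(seed)
  mc <- fisher.test(tab, simulate.p.value = TRUE, B = B)
  tibble(p_value = mc$p.value, method = "monte_carlo")
}

#' Refit-free subgroup evaluation of a model pair
#'
#' Scores both (already fitted) models on the full table, then computes each
#' model's AUC within every level of a stratifying column. Strata with fewer
#' than 5 events are flagged low-power; strata with a single outcome class are
#' skipped with a flag.
#'
#' @param data Patient features tibble containing the stratifier and outcome.
#' @param model_reference,model_optimized `timephen_logit` fits.
#' @param stratifier Column name to stratify by (e.g. `"mmrp_deficient"`,
#'   `"adjuvant_rt"`).
#' @param outcome Binary outcome column name.
#' @return A tibble: `stratum`, `n`, `n_events`, `auc_reference`,
#'   `auc_optimized`, `flag`.
#' @export
subgroup_evaluate <- function(data, model_reference, model_optimized,
                              stratifier, outcome = "relapse") {
  stopifnot(stratifier %in% names(data))
  sa <- predict(model_reference, data)
  sb <- predict(model_optimized, data)
  y <- as.numeric(data[[outcome]])
  purrr::map(unique(data[[stratifier]]), function(s) {
    idx <- which(data[[stratifier]] == s)
    n_ev <- sum(y[idx])
    if (length(unique(y[idx])) < 2) {
      return(tibble(stratum = as.character(s), n = length(idx), n_events = n_ev,
                    auc_reference = NA_real_, auc_optimized = NA_real_,
                    flag = "skipped: single outcome class"))
    }
    tibble(stratum = as.character(s), n = length(idx), n_events = n_ev,
           auc_reference = auc_mw(sa[idx], y[idx]),
           auc_optimized = auc_mw(sb[idx], y[idx]),
           flag = if (n_ev < 5) "low power (<5 events)" else "ok")
  }) |> dplyr::bind_rows()
}
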