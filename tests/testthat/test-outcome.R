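test_that("aggregate_patients derives carriage and purity per patient", {
  fx <- make_printed_margin_fixture()
  pf <- aggregate_patients(fx$assignments, fx$cohort)
  expect_equal(nrow(pf), 235)
  expect_equal(sum(pf$n_cores), 404)
  # a mixed two-core patient: carriage both, purity neither
  mixed <- tibble::tibble(core_id = c("Q1_c1", "Q1_c2"),
                          semantic_name = c("immune_desert", "immune_exclusion"))
  co <- cohort(make_cells(0),
               tibble::tibble(core_id = c("Q1_c1", "Q1_c2"), patient_id = "Q1",
                              diameter_mm = 1.2, area_mm2 = pi * 0.36),
               make_patient_row("Q1"))
  row <- aggregate_patients(mixed, co)
  expect_true(row$carriage_immune_desert & row$carriage_immune_exclusion)
  expect_false(row$purity_immune_desert | row$purity_immune_exclusion)
  # single-core patient: purity equals carriage
  single <- suppressWarnings(aggregate_patients(mixed[1, ], co))
  expect_true(single$purity_immune_desert)
})

test_that("filter_followup drops only short-follow-up non-relapsers", {
  pts <- dplyr::bind_rows(
    make_patient_row("A", relapse = FALSE, followup = 20),
    make_patient_row("B", relapse = TRUE, followup = 20),
    make_patient_row("C", relapse = FALSE, followup = 60)
  )
  kept <- filter_followup(pts)
  expect_setequal(kept$patient_id, c("B", "C"))
  expect_equal(attr(kept, "exclusions")$patient_id, "A")
})

test_that("fit_logistic matches the closed-form 2x2 log odds ratio and glm", {
  d2 <- tibble::tibble(x = rep(c(1, 1, 0, 0), c(10, 40, 30, 20)),
                       y = rep(c(1, 0, 1, 0), c(10, 40, 30, 20)))
  f <- fit_logistic(d2, "y", "x")
  expect_equal(unname(f$coefficients["x"]), log((10 * 20) / (40 * 30)),
               tolerance = 1e-8)
  set.seed(1)
  n <- 400
  d <- tibble::tibble(x1 = rnorm(n), x2 = rbinom(n, 1, 0.5))
  d$y <- rbinom(n, 1, plogis(-1 + 0.7 * d$x1 - 0.4 * d$x2))
  f2 <- fit_logistic(d, "y", c("x1", "x2"))
  g <- glm(y ~ x1 + x2, family = binomial(), data = d)
  expect_equal(unname(f2$coefficients), unname(coef(g)), tolerance = 1e-8)
  expect_equal(unname(sqrt(diag(f2$vcov))), unname(sqrt(diag(vcov(g)))),
               tolerance = 1e-6)
  expect_error(fit_logistic(dplyr::mutate(d, y = 0), "y", "x1"), "single class")
})

test_that("zero-signal covariates stay near zero; separation triggers the ridge", {
  set.seed(2)
  n <- 5000
  d <- tibble::tibble(x = rbinom(n, 1, 0.5), y = rbinom(n, 1, 0.2))
  f <- fit_logistic(d, "y", "x")
  expect_lt(abs(f$coefficients["x"]), 0.1)

  sep <- tibble::tibble(x = c(rep(0, 20), rep(1, 20)), y = c(rep(0, 20), rep(1, 20)))
  expect_message(fs <- fit_logistic(sep, "y", "x"), "ridge")
  expect_equal(fs$ridge_used, 1e-6)
})

test_that("planted outcome coefficients are recovered within 3 SE", {
  pf <- simulate_patient_features(synthetic_config(n_patients = 5000, rng_seed = 19))
  cfg <- synthetic_config()
  f <- fit_logistic(pf, "relapse", c("carriage_immune_exclusion", "purity_immune_exclusion"))
  planted <- c(cfg$outcome_beta0, cfg$outcome_beta_exclusion, cfg$outcome_beta_purity)
  se <- sqrt(diag(f$vcov))
  expect_true(all(abs(f$coefficients - planted) < 3 * se))
})

test_that("exhaustive_search enumerates subsets, is deterministic, and matches a direct refit", {
  pf <- encode_covariates(simulate_patient_features(synthetic_config(n_patients = 400, rng_seed = 3)))
  cand <- c("figo_num", "grade_num", "lvsi_num")
  es1 <- exhaustive_search(pf, "relapse", cand, seed = 21)
  es2 <- exhaustive_search(pf, "relapse", cand, seed = 21)
  expect_equal(nrow(es1$results), 7)   # 2^3 - 1
  expect_identical(es1$best_features, es2$best_features)
  expect_equal(es1$results$cv_error, es2$results$cv_error)
  # reference-covariate candidate set reproduces the directly fitted model
  direct <- fit_logistic(pf, "relapse", es1$best_features)
  expect_equal(es1$model$coefficients, direct$coefficients)
})

test_that("exhaustive_search selects the planted informative feature", {
  hits <- 0
  runs <- 12
  for (i in seq_len(runs)) {
    pf <- encode_covariates(simulate_patient_features(
      synthetic_config(n_patients = 1000, rng_seed = 3000 + i)))
    es <- exhaustive_search(pf, "relapse",
                            c("purity_immune_exclusion", "figo_num", "lvsi_num"),
                            seed = i)
    hits <- hits + ("purity_immune_exclusion" %in% es$best_features)
  }
  expect_gte(hits / runs, 0.9)
})

test_that("roc_auc matches the exhaustive pair-counting oracle", {
  r <- roc_auc(c(0.9, 0.8, 0.4, 0.3), c(1, 1, 0, 0))
  expect_equal(r$auc, 1)
  expect_equal(roc_auc(rep(0.5, 10), rep(c(0, 1), 5))$auc, 0.5)
  expect_error(roc_auc(1:3, c(1, 1, 1)))
  for (seed in 1:8) {
    set.seed(seed)
    n <- 200
    s <- sample(seq(0, 1, 0.05), n, replace = TRUE)  # force ties
    y <- rbinom(n, 1, 0.4)
    if (length(unique(y)) < 2) next
    expect_equal(roc_auc(s, y)$auc, pair_count_auc(s, y), tolerance = 1e-12)
  }
})

test_that("youden_stratify agrees with an exhaustive threshold scan", {
  s <- c(0.9, 0.8, 0.7, 0.4, 0.3, 0.1)
  y <- c(1, 1, 0, 1, 0, 0)
  got <- youden_stratify(s, y)
  # independent scan
  best <- -Inf; best_spec <- -Inf; best_cut <- NA
  for (cut in sort(unique(s))) {
    pred <- s >= cut
    sens <- sum(pred & y == 1) / sum(y == 1)
    spec <- sum(!pred & y == 0) / sum(y == 0)
    j <- sens + spec - 1
    if (j > best || (j == best && spec > best_spec)) {
      best <- j; best_spec <- spec; best_cut <- cut
    }
  }
  expect_equal(got$cutoff, best_cut)
  expect_equal(got$youden, best)

  sep <- youden_stratify(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_equal(sep$sensitivity, 1)
  expect_equal(sep$specificity, 1)
  # degenerate single-threshold case equals direct confusion arithmetic
  one <- youden_stratify(c(0.7, 0.7, 0.7, 0.2), c(1, 0, 1, 0))
  expect_equal(one$tp, 2); expect_equal(one$fp, 1); expect_equal(one$tn, 1)
})

test_that("predictive-value arithmetic matches confusion matrices algebraically", {
  expect_equal(ppv_npv_from_rates(1, 1, 0.3), tibble::tibble(ppv = 1, npv = 1))
  for (seed in 1:20) {
    set.seed(seed)
    tp <- sample(1:50, 1); fn <- sample(1:50, 1)
    fp <- sample(1:50, 1); tn <- sample(1:50, 1)
    sens <- tp / (tp + fn); spec <- tn / (tn + fp)
    prev <- (tp + fn) / (tp + fn + fp + tn)
    got <- ppv_npv_from_rates(sens, spec, prev)
    expect_equal(got$ppv, tp / (tp + fp), tolerance = 1e-12)
    expect_equal(got$npv, tn / (tn + fn), tolerance = 1e-12)
  }
})

test_that("bootstrap_compare applies the documented tie rule and detects dominance", {
  set.seed(4)
  y <- rbinom(100, 1, 0.3)
  s <- runif(100)
  bc <- bootstrap_compare(s, s, y, B = 200, seed = 5)
  expect_equal(bc$outperform_count, 0)
  expect_equal(bc$tie_count, 200)

  # anti-symmetry: with the same seed (same resamples), A's wins over B equal
  # B's losses to A, and wins + losses + ties account for every replicate
  s2 <- runif(100)
  bc_ab <- bootstrap_compare(s, s2, y, B = 400, seed = 6)
  bc_ba <- bootstrap_compare(s2, s, y, B = 400, seed = 6)
  expect_equal(bc_ab$tie_count, bc_ba$tie_count)
  expect_equal(bc_ab$outperform_count,
               bc_ba$B - bc_ba$tie_count - bc_ba$outperform_count)

  set.seed(7)
  y3 <- rep(c(1, 0), 100)
  perfect <- y3 + 0         # separates perfectly
  noise <- runif(200)
  bc3 <- bootstrap_compare(perfect, noise, y3, B = 200, seed = 8)
  expect_equal(bc3$outperform_count, 200)
})

test_that("km_estimate reproduces hand-computed product-limit curves", {
  km <- km_estimate(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$curves$survival, c(2 / 3, 1 / 3, 0))
  flat <- km_estimate(c(5, 6, 7), c(0, 0, 0))
  expect_true(all(flat$curves$survival == 1))
  # identical groups: log-rank statistic about zero
  same <- km_estimate(rep(c(1, 2, 3, 4), 2), rep(c(1, 0, 1, 0), 2),
                      rep(c("a", "b"), each = 4))
  expect_lt(same$logrank_chisq, 1e-10)
  expect_error(km_estimate(c(1, 2), c(1, 0), factor(c("a", "a"), levels = c("a", "b"))))
})

test_that("enrichment_test is exact for small tables and calibrated under the null", {
  got <- enrichment_test(matrix(c(3, 1, 1, 3), 2))
  expect_equal(got$p_value, 0.4857, tolerance = 1e-4)
  expect_equal(got$method, "exact")
  expect_error(enrichment_test(matrix(0, 2, 2)))
  expect_error(enrichment_test(matrix(c(0, 0, 2, 3), 2, byrow = TRUE)))

  # null calibration: under independent margins an exact test is valid
  # (super-uniform: P(p <= a) <= a up to Monte-Carlo error) while still
  # spreading mass across (0, 1) rather than clumping at 1
  set.seed(9)
  pvals <- replicate(1000, {
    a <- rbinom(1, 200, 0.5)
    b <- rbinom(1, 200, 0.5)
    enrichment_test(matrix(c(a, 200 - a, b, 200 - b), 2))$p_value
  })
  for (alpha in c(0.01, 0.05, 0.1, 0.25)) {
    mc_se <- sqrt(alpha * (1 - alpha) / length(pvals))
    expect_lte(mean(pvals <= alpha), alpha + 3 * mc_se)
  }
  expect_gt(mean(pvals <= 0.25), 0.1)   # not degenerate either
  expect_gt(mean(pvals), 0.45)
})

test_that("subgroup_evaluate stratifies fixed models and flags degenerate strata", {
  pf <- encode_covariates(simulate_patient_features(synthetic_config(n_patients = 800, rng_seed = 29)))
  ref <- fit_logistic(pf, "relapse", c("figo_num", "grade_num", "lvsi_num"))
  opt <- fit_logistic(pf, "relapse", c("carriage_immune_exclusion", "purity_immune_exclusion"))

  # constant stratifier reduces to the global evaluation
  pf$const <- "all"
  sg <- subgroup_evaluate(pf, ref, opt, "const")
  expect_equal(nrow(sg), 1)
  expect_equal(sg$auc_optimized, roc_auc(predict(opt, pf), pf$relapse)$auc)

  # single-class stratum is skipped with a flag
  pf$strat <- ifelse(seq_len(nrow(pf)) <= 10 & !pf$relapse, "tiny", "rest")
  sg2 <- subgroup_evaluate(pf, ref, opt, "strat")
  expect_true(any(grepl("skipped", sg2$flag)))
})

test_that("a planted stratum-specific effect yields a larger AUC gap in that stratum", {
  set.seed(30)
  wins <- replicate(30, {
    n <- 400
    strat <- rep(c("s1", "s2"), each = n / 2)
    x <- rbinom(n, 1, 0.3)
    p <- ifelse(strat == "s1", plogis(-2.5 + 2.5 * x), plogis(-2.2))
    y <- rbinom(n, 1, p)
    if (min(table(y[strat == "s1"])) == 0 || min(table(y[strat == "s2"])) == 0) return(NA)
    d <- tibble::tibble(x = x, y = y)
    m <- fit_logistic(d, "y", "x")
    null_m <- fit_logistic(dplyr::mutate(d, z = rnorm(n)), "y", "z")
    sg <- subgroup_evaluate(dplyr::mutate(d, strat = strat, z = rnorm(n)),
                            null_m, m, "strat", outcome = "y")
    gap <- sg$auc_optimized - sg$auc_reference
    gap[sg$stratum == "s1"] > gap[sg$stratum == "s2"]
  })
  expect_gt(mean(wins, na.rm = TRUE), 0.75)
})
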