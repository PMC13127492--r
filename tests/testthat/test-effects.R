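test_that("stable-edge selection is inclusive at the threshold and capped", {
  cand <- data.frame(
    predictor = c("a", "b", "c", "d", "e"), outcome = c(rep("use", 3), "alt", "alt"),
    stability = c(0.9, 0.6, 0.59, 0.8, 0.7), mean_coef = c(0.3, 0.2, 0.5, 0.1, 0.4),
    selection_count = c(90, 60, 59, 80, 70), n_bootstrap = 100)
  kept <- select_stable_edges(cand, effect_config(stability_threshold = 0.6))
  expect_setequal(kept$predictor, c("a", "b", "d", "e"))
  one <- select_stable_edges(cand, effect_config(stability_threshold = 0.6,
                                                 max_edges_per_outcome = 1))
  expect_setequal(one$predictor, c("a", "d"))
  none <- select_stable_edges(cand, effect_config(stability_threshold = 0.95))
  expect_equal(nrow(none), 0)
})

test_that("estimation splits subjects, never rows", {
  panel <- data.frame(subject_id = rep(paste0("s", 1:10), each = 3),
                      step = rep(0:2, 10), y_use = 0, m_use = 1, p = rnorm(30))
  cfg <- effect_config(holdout_fraction = 0.2, seed = 5)
  sp <- make_estimation_split(panel, cfg)
  expect_equal(length(unique(sp$estimation$subject_id)), 8)
  expect_equal(length(unique(sp$test$subject_id)), 2)
  expect_length(intersect(sp$estimation$subject_id, sp$test$subject_id), 0)
  # all of a subject's rows land on one side
  expect_equal(nrow(sp$estimation) + nrow(sp$test), nrow(panel))
  # determinism and the no-holdout case
  sp2 <- make_estimation_split(panel, cfg)
  expect_identical(sp$test$subject_id, sp2$test$subject_id)
  all_in <- make_estimation_split(panel, effect_config(holdout_fraction = 0))
  expect_equal(nrow(all_in$estimation), nrow(panel))
  expect_error(make_estimation_split(panel[panel$subject_id == "s1", ],
                                     effect_config(holdout_fraction = 0.9)),
               "fewer than 2")
})

test_that("the DML frame excludes the treatment from the covariates", {
  sim <- simulate_panel(small_sim_config(seed = 19))
  rows <- select_at_risk_rows(build_lagged_features(sim$panel, lag_spec(2)),
                              "use")
  fr <- build_dml_frame(rows, "pred_001_L1", "use", effect_config())
  expect_false("pred_001_L1" %in% colnames(fr$x))
  expect_true("pred_001_L2" %in% colnames(fr$x))
  expect_equal(length(fr$y), length(fr$d))
  expect_equal(length(fr$y), nrow(fr$x))
  expect_equal(length(fr$groups), length(fr$y))
  # treatment standardized on these rows
  expect_lt(abs(mean(fr$d)), 1e-8)
  expect_lt(abs(sd(fr$d) - 1), 1e-8)
  # the switch drops every lag of the treatment's base variable
  fr2 <- build_dml_frame(rows, "pred_001_L1", "use",
                         effect_config(exclude_treatment_lags = TRUE))
  expect_false(any(grepl("^pred_001_", colnames(fr2$x))))
})

test_that("cross-fitting is orthogonal and never predicts a subject from itself", {
  sim <- simulate_panel(small_sim_config(seed = 23, n_subjects = 600L,
                                         missing_rate = 0))
  rows <- select_at_risk_rows(build_lagged_features(sim$panel, lag_spec(2)),
                              "use")
  fr <- build_dml_frame(rows, "pred_003_L1", "use",
                        effect_config(nuisance_learner = "linear"))
  cfg <- effect_config(nuisance_learner = "linear", seed = 3)
  res <- crossfit_residualize(fr, cfg)
  # every subject sits in exactly one fold and each row is predicted
  expect_false(any(is.na(res$y_res)))
  expect_false(any(is.na(res$d_res)))
  fold_per_subj <- tapply(res$fold, fr$groups, function(f) length(unique(f)))
  expect_true(all(fold_per_subj == 1))
  expect_equal(unname(res$fold_of[fr$groups]), res$fold)
  # orthogonality: treatment residuals uncorrelated with the covariates
  expect_lt(abs(mean(res$d_res)), 3 / sqrt(length(res$d_res)))
  cors <- abs(cor(res$d_res, fr$x))
  expect_lt(max(cors, na.rm = TRUE), 4 / sqrt(length(res$d_res)))
})

test_that("forest nuisances keep binary-outcome residuals within [-1, 1]", {
  set.seed(41)
  rows <- data.frame(subject_id = rep(paste0("s", 1:40), each = 2),
                     step = rep(1:2, 40), y_use = rbinom(80, 1, 0.3), m_use = 1,
                     a_L1 = rnorm(80), b_L1 = rnorm(80), d_L1 = rnorm(80))
  fr <- build_dml_frame(rows, "d_L1", "use", effect_config(max_lag = 1))
  cfg <- effect_config(nuisance_learner = "random_forest", num_trees = 50,
                       n_folds = 2, seed = 4)
  res <- crossfit_residualize(fr, cfg)
  # forest predictions average training labels in [0, 1]
  expect_true(all(res$y_res >= -1 & res$y_res <= 1))
})

test_that("two subjects and two folds reduce to leave-one-subject-out", {
  set.seed(31)
  rows <- data.frame(subject_id = rep(c("a", "b"), each = 6),
                     step = rep(1:6, 2), y_use = rbinom(12, 1, 0.5), m_use = 1,
                     x1_L1 = rnorm(12), x2_L1 = rnorm(12), d_L1 = rnorm(12))
  fr <- build_dml_frame(rows, "d_L1", "use",
                        effect_config(max_lag = 1, n_folds = 2))
  cfg <- effect_config(nuisance_learner = "linear", n_folds = 2, seed = 9)
  res <- crossfit_residualize(fr, cfg)
  # recompute by hand: each subject's predictions come from a model fit
  # solely on the other subject
  for (s in c("a", "b")) {
    test <- fr$groups == s
    cf <- stats::lm.fit(cbind(1, fr$x[!test, ]), fr$y[!test])$coefficients
    cf[is.na(cf)] <- 0
    pred <- drop(cbind(1, fr$x[test, ]) %*% cf)
    expect_equal(res$y_res[test], fr$y[test] - pred, tolerance = 1e-10)
  }
  expect_error(crossfit_residualize(fr, effect_config(n_folds = 3)),
               "fewer distinct subjects")
})

test_that("the residual regression slope matches its closed form and an OLS oracle", {
  expect_equal(estimate_theta(c(2, -2), c(1, -1))$theta, 2)
  fit <- estimate_theta(0.5 * c(1, 2, -3), c(1, 2, -3))
  expect_equal(fit$theta, 0.5)
  expect_equal(fit$residuals, rep(0, 3))
  set.seed(12)
  for (i in 1:20) {
    y <- rnorm(50); d <- rnorm(50)
    # no intercept: brute-force normal equations
    expect_equal(estimate_theta(y, d)$theta,
                 solve(crossprod(d), crossprod(d, y))[1, 1],
                 tolerance = 1e-10)
    # with intercept: full OLS
    fit_i <- estimate_theta(y, d, include_intercept = TRUE)
    ref <- lm(y ~ d)
    expect_equal(fit_i$theta, unname(coef(ref)[2]), tolerance = 1e-10)
    expect_equal(fit_i$intercept, unname(coef(ref)[1]), tolerance = 1e-10)
  }
  expect_error(estimate_theta(c(1, 2), c(0, 0)), "identically zero")
})

test_that("cluster-robust variance matches a brute-force sum over clusters", {
  for (i in 1:25) {
    dat <- random_cluster_data(n_clusters = 5 + i %% 7,
                               rows_per_cluster = 2 + i %% 4, seed = 100 + i)
    fit <- estimate_theta(dat$y, dat$d)
    se <- cluster_robust_se(dat$d, fit$residuals, dat$groups)
    # independent brute-force: explicit loop over clusters
    bread <- 1 / sum(dat$d^2)
    meat <- 0
    for (g in unique(dat$groups)) {
      in_g <- dat$groups == g
      meat <- meat + sum(dat$d[in_g] * fit$residuals[in_g])^2
    }
    G <- length(unique(dat$groups))
    expect_equal(se, sqrt(G / (G - 1) * bread^2 * meat), tolerance = 1e-10)
    # intercept case against the matrix sandwich computed longhand
    fit_i <- estimate_theta(dat$y, dat$d, include_intercept = TRUE)
    se_i <- cluster_robust_se(dat$d, fit_i$residuals, dat$groups,
                              include_intercept = TRUE)
    z <- cbind(1, dat$d)
    b <- solve(t(z) %*% z)
    m <- matrix(0, 2, 2)
    for (g in unique(dat$groups)) {
      in_g <- dat$groups == g
      s_g <- t(z[in_g, , drop = FALSE]) %*% fit_i$residuals[in_g]
      m <- m + s_g %*% t(s_g)
    }
    v <- G / (G - 1) * b %*% m %*% b
    expect_equal(se_i, sqrt(v[2, 2]), tolerance = 1e-10)
  }
})

test_that("with singleton clusters the sandwich reduces to the HC estimator", {
  dat <- random_cluster_data(n_clusters = 200, rows_per_cluster = 1, seed = 77)
  fit <- estimate_theta(dat$y, dat$d)
  se <- cluster_robust_se(dat$d, fit$residuals, dat$groups)
  # HC0 variance for the no-intercept regression, via the sandwich package
  ref <- lm(dat$y ~ dat$d - 1)
  hc0 <- sqrt(sandwich::vcovHC(ref, type = "HC0")[1, 1])
  G <- 200
  expect_equal(se, hc0 * sqrt(G / (G - 1)), tolerance = 1e-10)
  expect_error(cluster_robust_se(dat$d, fit$residuals, rep("one", 200)),
               "single cluster")
  # zero residuals give zero standard error
  expect_equal(cluster_robust_se(dat$d, rep(0, 200), dat$groups), 0)
})

test_that("duplicating every cluster changes the variance as the closed form dictates", {
  dat <- random_cluster_data(n_clusters = 30, rows_per_cluster = 3, seed = 55)
  fit <- estimate_theta(dat$y, dat$d)
  d2 <- c(dat$d, dat$d); y2 <- c(dat$y, dat$y)
  g2 <- c(dat$groups, paste0(dat$groups, "_copy"))
  fit2 <- estimate_theta(y2, d2)
  expect_equal(fit2$theta, fit$theta, tolerance = 1e-12)
  se2 <- cluster_robust_se(d2, fit2$residuals, g2)
  # closed form: bread halves, meat doubles, G doubles
  bread <- 1 / sum(dat$d^2)
  meat <- sum(rowsum(dat$d * fit$residuals, dat$groups)^2)
  expect_equal(se2, sqrt((60 / 59) * (bread / 2)^2 * (2 * meat)),
               tolerance = 1e-10)
})

test_that("edge effects assemble theta, sandwich CI and bookkeeping", {
  sim <- simulate_panel(small_sim_config(seed = 29, n_subjects = 500L))
  panel <- build_lagged_features(sim$panel, lag_spec(2))
  cfg <- effect_config(nuisance_learner = "linear", holdout_fraction = 0,
                       seed = 2)
  eff <- estimate_edge_effect(panel, "pred_001_L1", "use", cfg, stability = 0.9)
  expect_s3_class(eff, "effect_estimate")
  expect_true(eff$ci_low <= eff$theta && eff$theta <= eff$ci_high)
  z <- qnorm(0.975)
  expect_equal(eff$ci_low, eff$theta - z * eff$se)
  expect_equal(eff$ci_high, eff$theta + z * eff$se)
  expect_lte(eff$n_subjects, eff$n_rows)
  expect_equal(eff$stability, 0.9)
  # confidence-interval arithmetic at stated numbers
  expect_equal(0.01 - z * 0.004, 0.00216, tolerance = 1e-3)
  expect_equal(0.01 + z * 0.004, 0.01784, tolerance = 1e-3)
})

test_that("estimate_effects skips ineligible outcomes with reasons", {
  sim <- simulate_panel(small_sim_config(seed = 33, n_subjects = 100L))
  panel <- build_lagged_features(sim$panel, lag_spec(2))
  edges <- data.frame(predictor = "pred_001_L1", outcome = "use",
                      stability = 0.9)
  eff <- estimate_effects(panel, edges, effect_config(nuisance_learner = "linear"),
                          min_rows = 10000L)
  expect_equal(nrow(eff), 0)
  skipped <- attr(eff, "skipped")
  expect_equal(skipped$reason, "too_few_rows")
})
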