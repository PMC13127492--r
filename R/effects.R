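#' Configuration for effect estimation
#'
#' Knobs for the second stage: partialling-out estimation of the adjusted
#' effect of one lagged predictor (the treatment) on an interval-level
#' initiation outcome, with cross-fitted machine-learning nuisance models
#' and cluster-robust inference.
#'
#' @param stability_threshold minimum bootstrap stability for an edge to be
#'   estimated (default 0.6).
#' @param max_edges_per_outcome cap on estimated edges per outcome.
#' @param n_folds cross-fitting folds; folds partition subjects, not rows.
#' @param nuisance_learner `"random_forest"` (regression forests for both
#'   nuisance functions, including the binary outcome) or `"linear"`
#'   (least squares).
#' @param num_trees,min_node_size random-forest hyperparameters.
#' @param ci_level confidence level for the interval (normal quantiles;
#'   cluster counts are large in the target regime).
#' @param include_intercept include an intercept in the residual-on-residual
#'   regression; off by default because cross-fitted residuals are
#'   approximately centered by construction.
#' @param exclude_treatment_lags drop every lag of the treatment's base
#'   variable from the covariates, not just the treatment column itself;
#'   default `FALSE` (only the treatment column is excluded).
#' @param holdout_fraction fraction of subjects held out as an untouched
#'   test split before estimation.
#' @param max_lag lag order of the covariate set.
#' @param deltas include `_D1` change features among covariates.
#' @param seed integer seed.
#' @return an object of class `effect_config`.
#' @export
effect_config <- function(stability_threshold = 0.6, max_edges_per_outcome = 25L,
                          n_folds = 5L,
                          nuisance_learner = c("random_forest", "linear"),
                          num_trees = 500L, min_node_size = 5L,
                          ci_level = 0.95, include_intercept = FALSE,
                          exclude_treatment_lags = FALSE,
                          holdout_fraction = 0.2, max_lag = 2L,
                          deltas = FALSE, seed = 1L) {
  nuisance_learner <- match.arg(nuisance_learner)
  # thresholds above 1 are allowed: they deliberately select no edge
  stopifnot(stability_threshold >= 0,
            max_edges_per_outcome >= 1, n_folds >= 2,
            ci_level > 0, ci_level < 1,
            holdout_fraction >= 0, holdout_fraction < 1, max_lag >= 1)
  structure(list(stability_threshold = stability_threshold,
                 max_edges_per_outcome = as.integer(max_edges_per_outcome),
                 n_folds = as.integer(n_folds),
                 nuisance_learner = nuisance_learner,
                 num_trees = as.integer(num_trees),
                 min_node_size = as.integer(min_node_size),
                 ci_level = ci_level, include_intercept = include_intercept,
                 exclude_treatment_lags = exclude_treatment_lags,
                 holdout_fraction = holdout_fraction,
                 max_lag = as.integer(max_lag), deltas = deltas,
                 seed = as.integer(seed)),
            class = "effect_config")
}

#' Keep the stable edges, capped per outcome
#'
#' Retains candidates with stability at or above the threshold (inclusive),
#' then keeps at most `max_edges_per_outcome` per outcome in the
#' [rank_edges()] ordering.
#'
#' @param candidates edge-candidate data.frame from [bootstrap_stability()].
#' @param config an [effect_config()].
#' @return the retained edges (possibly zero rows).
#' @export
select_stable_edges <- function(candidates, config = effect_config()) {
  keep <- candidates[candidates$stability >= config$stability_threshold, ,
                     drop = FALSE]
  if (nrow(keep) == 0) return(keep)
  parts <- lapply(split(keep, keep$outcome), rank_edges,
                  top_k = config$max_edges_per_outcome)
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

#' Split subjects into estimation and held-out test sets
#'
#' Subjects (never individual rows) are randomly assigned so that all of a
#' subject's repeated measures fall on one side; estimation proceeds on the
#' estimation side only.
#'
#' @param panel a panel data.frame.
#' @param config an [effect_config()]; uses `holdout_fraction` and `seed`.
#' @return list with `estimation` and `test` data.frames.
#' @export
make_estimation_split <- function(panel, config = effect_config()) {
  subj <- unique(panel$subject_id)
  n_test <- floor(config$holdout_fraction * length(subj))
  if (length(subj) - n_test < 2)
    stop("holdout_fraction leaves fewer than 2 estimation subjects")
  set.seed(config$seed)
  test_subj <- if (n_test > 0) sample(subj, n_test) else character(0)
  in_test <- panel$subject_id %in% test_subj
  list(estimation = panel[!in_test, , drop = FALSE],
       test = panel[in_test, , drop = FALSE])
}

#' Assemble the estimation frame for one edge
#'
#' Builds the outcome vector `Y`, the treatment `D` (the edge's lagged
#' predictor, imputed and standardized on these rows so the effect reads per
#' 1 SD), the covariate matrix `X` (all lagged variables up to the same lag
#' order, excluding the treatment, preprocessed), and the subject grouping.
#'
#' @param rows at-risk rows for the edge's outcome (`m = 1`, `step >= 1`).
#' @param treatment lagged predictor column name.
#' @param outcome outcome name.
#' @param config an [effect_config()].
#' @return a `dml_frame`: list with `y`, `d`, `x`, `groups`, `treatment`,
#'   `outcome`.
#' @export
build_dml_frame <- function(rows, treatment, outcome, config = effect_config()) {
  if (!treatment %in% names(rows)) stop("unknown treatment column: ", treatment)
  y <- rows[[paste0("y_", outcome)]]
  if (is.null(y)) stop("unknown outcome: ", outcome)
  covars <- lagged_columns(rows, config$max_lag, config$deltas)
  drop_cols <- if (config$exclude_treatment_lags) {
    base <- sub("_(L[0-9]+|D1)$", "", treatment)
    grep(paste0("^", base, "_(L[0-9]+|D1)$"), covars, value = TRUE)
  } else treatment
  covars <- setdiff(covars, drop_cols)
  if (length(covars) == 0) stop("no covariates left after exclusions")
  d_fm <- preprocess(rows, treatment)
  if (is.na(d_fm$sds[1])) stop("treatment '", treatment, "' is constant")
  fm <- preprocess(rows, covars)
  structure(list(y = as.numeric(y), d = as.numeric(d_fm$x[, 1]), x = fm$x,
                 groups = as.character(rows$subject_id),
                 treatment = treatment, outcome = outcome),
            class = "dml_frame")
}

fit_nuisance <- function(x, target, config, seed) {
  if (config$nuisance_learner == "random_forest") {
    fit <- ranger::ranger(x = as.data.frame(x), y = target,
                          num.trees = config$num_trees,
                          min.node.size = config$min_node_size,
                          seed = seed, num.threads = 1L)
    function(newx) stats::predict(fit, data = as.data.frame(newx),
                                  num.threads = 1L)$predictions
  } else {
    cf <- stats::lm.fit(cbind(1, x), target)$coefficients
    cf[is.na(cf)] <- 0
    function(newx) drop(cbind(1, newx) %*% cf)
  }
}

#' Cross-fitted residualization of outcome and treatment
#'
#' Partitions subjects into `n_folds` groups; for each fold, the outcome
#' model `m(X) = E[Y | X]` and the treatment model `g(X) = E[D | X]` are fit
#' on the out-of-fold rows with the configured learner and predicted on the
#' in-fold rows, yielding residuals `Y - m(X)` and `D - g(X)`. Every row's
#' predictions come from models never trained on any row of that row's
#' subject, which removes own-observation overfitting bias from the
#' downstream effect estimate.
#'
#' @param frame a `dml_frame` from [build_dml_frame()].
#' @param config an [effect_config()].
#' @return list with `y_res`, `d_res`, `fold` (per-row fold id), and
#'   `fold_of` (named fold assignment per subject).
#' @export
crossfit_residualize <- function(frame, config = effect_config()) {
  stopifnot(inherits(frame, "dml_frame"))
  subj <- unique(frame$groups)
  if (length(subj) < config$n_folds)
    stop("fewer distinct subjects (", length(subj), ") than folds (",
         config$n_folds, ")")
  set.seed(config$seed)
  fold_of <- stats::setNames(sample(rep_len(seq_len(config$n_folds),
                                            length(subj))), subj)
  fold <- as.integer(fold_of[frame$groups])
  y_res <- d_res <- rep(NA_real_, length(frame$y))
  for (k in seq_len(config$n_folds)) {
    test <- fold == k
    if (!any(test)) stop("fold ", k, " has zero rows")
    train <- !test
    # hygiene: no training row may share a subject with a test row
    if (length(intersect(frame$groups[train], frame$groups[test])) > 0)
      stop("internal error: subject present in both train and test folds")
    m_hat <- fit_nuisance(frame$x[train, , drop = FALSE], frame$y[train],
                          config, seed = config$seed + k)
    g_hat <- fit_nuisance(frame$x[train, , drop = FALSE], frame$d[train],
                          config, seed = config$seed + config$n_folds + k)
    y_res[test] <- frame$y[test] - m_hat(frame$x[test, , drop = FALSE])
    d_res[test] <- frame$d[test] - g_hat(frame$x[test, , drop = FALSE])
  }
  list(y_res = y_res, d_res = d_res, fold = fold, fold_of = fold_of)
}

#' Residual-on-residual effect estimate
#'
#' The adjusted effect is the slope of the residualized outcome on the
#' residualized treatment. Without an intercept it has the closed form
#' `theta = sum(d_res * y_res) / sum(d_res^2)`; with an intercept it is the
#' ordinary least-squares slope.
#'
#' @param y_res,d_res residual vectors of equal length >= 2.
#' @param include_intercept logical.
#' @return list with `theta`, `intercept` (0 when not requested), and
#'   `residuals` (`y_res - theta * d_res - intercept`).
#' @export
estimate_theta <- function(y_res, d_res, include_intercept = FALSE) {
  stopifnot(length(y_res) == length(d_res), length(y_res) >= 2)
  if (sum(d_res^2) == 0)
    stop("treatment residuals are identically zero: treatment is fully ",
         "explained by the covariates")
  if (include_intercept) {
    dc <- d_res - mean(d_res)
    if (sum(dc^2) == 0) stop("treatment residuals are constant")
    theta <- sum(dc * (y_res - mean(y_res))) / sum(dc^2)
    a <- mean(y_res) - theta * mean(d_res)
  } else {
    theta <- sum(d_res * y_res) / sum(d_res^2)
    a <- 0
  }
  list(theta = theta, intercept = a,
       residuals = y_res - theta * d_res - a)
}

#' Cluster-robust sandwich standard error for the effect
#'
#' Aggregates score contributions within subject clusters. For the
#' no-intercept regression the variance is
#' `(sum d^2)^-2 * sum_g (sum_{i in g} d_i e_i)^2`, scaled by the
#' small-sample factor `G / (G - 1)`; with an intercept the matrix sandwich
#' analogue is used and the slope's standard error returned.
#'
#' @param d_res treatment residuals.
#' @param epsilon residuals from the effect regression.
#' @param groups cluster (subject) identifier per row.
#' @param include_intercept must match the effect regression.
#' @return the standard error (a non-negative number).
#' @export
cluster_robust_se <- function(d_res, epsilon, groups, include_intercept = FALSE) {
  stopifnot(length(d_res) == length(epsilon), length(d_res) == length(groups))
  g <- factor(groups)
  G <- nlevels(g)
  if (G < 2) stop("cluster-robust variance undefined with a single cluster")
  corr <- G / (G - 1)
  if (!include_intercept) {
    bread <- 1 / sum(d_res^2)
    score <- rowsum(d_res * epsilon, g)
    sqrt(corr * bread^2 * sum(score^2))
  } else {
    z <- cbind(1, d_res)
    bread <- solve(crossprod(z))
    scores <- rowsum(z * epsilon, g)        # G x 2 cluster score sums
    meat <- crossprod(scores)
    v <- corr * (bread %*% meat %*% bread)
    sqrt(v[2, 2])
  }
}

#' Estimate the adjusted effect of one stable edge
#'
#' Composes the full second stage for a (lagged predictor, outcome) edge:
#' at-risk row selection, frame construction, cross-fitted residualization,
#' the residual-on-residual slope, and cluster-robust confidence limits.
#'
#' @param panel a panel data.frame with lagged columns (typically the
#'   estimation side of [make_estimation_split()]).
#' @param treatment lagged predictor column name.
#' @param outcome outcome name.
#' @param config an [effect_config()].
#' @param stability optional stability score carried from discovery.
#' @return an `effect_estimate` one-row data.frame: `predictor`, `outcome`,
#'   `theta` (probability-scale effect per 1 SD of the treatment), `se`,
#'   `ci_low`, `ci_high`, `n_rows`, `n_subjects`, `n_folds_used`,
#'   `stability`.
#' @export
estimate_edge_effect <- function(panel, treatment, outcome,
                                 config = effect_config(), stability = NA_real_) {
  rows <- select_at_risk_rows(panel, outcome)
  frame <- build_dml_frame(rows, treatment, outcome, config)
  res <- crossfit_residualize(frame, config)
  fit <- estimate_theta(res$y_res, res$d_res, config$include_intercept)
  se <- cluster_robust_se(res$d_res, fit$residuals, frame$groups,
                          config$include_intercept)
  z <- stats::qnorm(1 - (1 - config$ci_level) / 2)
  out <- data.frame(predictor = treatment, outcome = outcome,
                    theta = fit$theta, se = se,
                    ci_low = fit$theta - z * se, ci_high = fit$theta + z * se,
                    n_rows = length(frame$y),
                    n_subjects = length(unique(frame$groups)),
                    n_folds_used = config$n_folds, stability = stability,
                    stringsAsFactors = FALSE)
  class(out) <- c("effect_estimate", "data.frame")
  out
}

#' Estimate effects for a set of stable edges
#'
#' Runs [estimate_edge_effect()] for each retained edge; edges whose
#' outcome fails eligibility on the estimation rows are skipped with the
#' reason recorded.
#'
#' @param panel panel with lagged columns (estimation split).
#' @param edges data.frame with `predictor`, `outcome` (and optionally
#'   `stability`) columns, e.g. from [select_stable_edges()].
#' @param config an [effect_config()].
#' @param min_rows,prevalence_bounds eligibility thresholds applied per
#'   outcome before estimation.
#' @return an effects data.frame (zero rows if nothing estimable) with the
#'   skip log attached as attribute `"skipped"`.
#' @export
estimate_effects <- function(panel, edges, config = effect_config(),
                             min_rows = 500L,
                             prevalence_bounds = c(0.005, 0.995)) {
  out <- list(); skipped <- list()
  for (i in seq_len(nrow(edges))) {
    e <- edges[i, ]
    rows <- select_at_risk_rows(panel, e$outcome)
    rep <- check_eligibility(rows, e$outcome, min_rows, prevalence_bounds)
    if (!rep$passed) {
      skipped[[length(skipped) + 1L]] <-
        data.frame(predictor = e$predictor, outcome = e$outcome,
                   reason = paste(rep$failure_reasons, collapse = ";"),
                   stringsAsFactors = FALSE)
      next
    }
    st <- if ("stability" %in% names(e)) e$stability else NA_real_
    out[[length(out) + 1L]] <-
      estimate_edge_effect(panel, e$predictor, e$outcome, config, st)
  }
  effects <- if (length(out) > 0) do.call(rbind, out)
  else data.frame(predictor = character(0), outcome = character(0),
                  theta = numeric(0), se = numeric(0), ci_low = numeric(0),
                  ci_high = numeric(0), n_rows = integer(0),
                  n_subjects = integer(0), n_folds_used = integer(0),
                  stability = numeric(0), stringsAsFactors = FALSE)
  rownames(effects) <- NULL
  attr(effects, "skipped") <- if (length(skipped) > 0) do.call(rbind, skipped)
  else NULL
  class(effects) <- c("effect_estimate", "data.frame")
  effects
}
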