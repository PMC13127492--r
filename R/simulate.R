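#' Configuration for the synthetic panel generator
#'
#' Builds a validated configuration for [simulate_panel()]. The generator
#' emulates a large longitudinal cohort in which each subject contributes one
#' row per discrete follow-up interval ("step"), time-varying predictors
#' evolve as stationary Gaussian AR(1) processes with block-equicorrelated
#' cross-sections, a subject-level latent confounder loads on a subset of
#' predictors and on the hazard, and rare binary initiation outcomes follow a
#' discrete-time logistic hazard in the previous interval's predictor values.
#' Initiation is absorbing: after a subject's first event for an outcome the
#' at-risk indicator drops to zero and later rows are excluded for it.
#'
#' @param n_subjects number of subjects (default 10000, a cohort-scale panel).
#' @param n_steps number of follow-up intervals per subject, indexed from 0.
#' @param n_predictors number of time-varying predictor columns.
#' @param n_causal number of predictors with true lag-1 effects on the hazard.
#' @param hazard_intercepts named numeric vector, one per outcome, on the
#'   logit scale. Names become outcome names (`y_<name>`, `m_<name>` columns).
#' @param causal_coefs named numeric vector mapping predictor names to
#'   log-odds per 1 SD of the lag-1 predictor. `NULL` assigns default
#'   coefficients of magnitude 0.5--0.8 with alternating sign to the first
#'   `n_causal` predictors.
#' @param lag2_coefs optional named numeric vector of additional lag-2
#'   log-odds effects (for stress-testing larger lag orders); default none.
#' @param predictor_autocorr AR(1) coefficient in `[0, 1)` for each predictor.
#' @param predictor_block_corr within-block cross-sectional correlation in
#'   `[0, 1)`.
#' @param block_size number of predictors per correlated block.
#' @param confounder_strength coefficient of the latent subject-level
#'   confounder on the hazard logit (>= 0).
#' @param confounder_loading loading of the confounder on each confounded
#'   predictor, in `[0, 1)`; predictor variance is kept at 1.
#' @param n_confounded number of predictors the confounder loads on; default
#'   `2 * n_causal` (the causal predictors plus as many non-causal ones).
#' @param missing_rate MCAR missingness rate applied to predictor cells.
#' @param seed integer seed; generation is fully reproducible from it.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 10000L, n_steps = 5L, n_predictors = 200L,
                       n_causal = 5L,
                       hazard_intercepts = c(use = stats::qlogis(0.05)),
                       causal_coefs = NULL, lag2_coefs = NULL,
                       predictor_autocorr = 0.5, predictor_block_corr = 0.3,
                       block_size = 10L, confounder_strength = 0.5,
                       confounder_loading = 0.4, n_confounded = NULL,
                       missing_rate = 0.02, seed = 1L) {
  stopifnot(n_subjects >= 1, n_steps >= 1, n_predictors >= 1,
            n_causal >= 0, n_causal <= n_predictors,
            predictor_autocorr >= 0, predictor_autocorr < 1,
            predictor_block_corr >= 0, predictor_block_corr < 1,
            block_size >= 1, confounder_strength >= 0,
            confounder_loading >= 0, confounder_loading < 1,
            missing_rate >= 0, missing_rate < 1)
  if (is.null(names(hazard_intercepts)) || any(!nzchar(names(hazard_intercepts))))
    stop("hazard_intercepts must be a named vector (names are outcome names)")
  if (any(stats::plogis(hazard_intercepts) >= 0.5))
    stop("hazard intercept implies a per-interval event probability >= 0.5; ",
         "the generator targets the rare-event regime")
  pred_names <- sprintf("pred_%03d", seq_len(n_predictors))
  if (is.null(causal_coefs)) {
    base <- c(0.8, -0.6, 0.5, 0.7, -0.5)
    causal_coefs <- if (n_causal > 0)
      stats::setNames(rep_len(base, n_causal), pred_names[seq_len(n_causal)])
    else stats::setNames(numeric(0), character(0))
  }
  if (!all(names(causal_coefs) %in% pred_names))
    stop("causal_coefs names must be predictor names (pred_001, ...)")
  if (!is.null(lag2_coefs) && !all(names(lag2_coefs) %in% pred_names))
    stop("lag2_coefs names must be predictor names")
  if (is.null(n_confounded)) n_confounded <- min(2L * n_causal, n_predictors)
  structure(list(
    n_subjects = as.integer(n_subjects), n_steps = as.integer(n_steps),
    n_predictors = as.integer(n_predictors), n_causal = as.integer(n_causal),
    hazard_intercepts = hazard_intercepts, causal_coefs = causal_coefs,
    lag2_coefs = lag2_coefs %||% stats::setNames(numeric(0), character(0)),
    predictor_autocorr = predictor_autocorr,
    predictor_block_corr = predictor_block_corr,
    block_size = as.integer(block_size),
    confounder_strength = confounder_strength,
    confounder_loading = confounder_loading,
    n_confounded = as.integer(n_confounded),
    missing_rate = missing_rate, seed = as.integer(seed),
    predictor_names = pred_names
  ), class = "sim_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Stationary cross-sectional draw of the predictor innovations: within each
# block of `block_size` predictors the correlation is predictor_block_corr,
# achieved by a shared block factor. Returns an n x p matrix with unit
# variance columns.
draw_cross_section <- function(n, config) {
  p <- config$n_predictors
  r <- config$predictor_block_corr
  block <- (seq_len(p) - 1L) %/% config$block_size + 1L
  n_block <- max(block)
  f <- matrix(stats::rnorm(n * n_block), n, n_block)
  e <- matrix(stats::rnorm(n * p), n, p)
  sqrt(r) * f[, block, drop = FALSE] + sqrt(1 - r) * e
}

# Indices of predictors the latent confounder loads on: the causal predictors
# first, then the next non-causal ones, up to n_confounded.
confounded_indices <- function(config) {
  causal_idx <- match(names(config$causal_coefs), config$predictor_names)
  extra <- setdiff(seq_len(config$n_predictors), causal_idx)
  idx <- c(causal_idx, extra)[seq_len(min(config$n_confounded,
                                          config$n_predictors))]
  sort(idx)
}

# The generating mechanism: latent confounder, AR(1) predictors, logistic
# hazards with absorbing initiation. Returns the pre-missingness truth.
# Internal; simulate_panel() formats it as a tidy table and
# true_effect_oracle() evaluates hazards on it directly.
sim_mechanism <- function(config) {
  set.seed(config$seed)
  n <- config$n_subjects; tt <- config$n_steps
  rho <- config$predictor_autocorr
  lam <- config$confounder_loading
  conf_idx <- confounded_indices(config)

  u <- stats::rnorm(n)                      # latent subject confounder
  x <- vector("list", tt)                   # true predictor values per step
  x[[1]] <- draw_cross_section(n, config)
  if (tt > 1) for (t in 2:tt)
    x[[t]] <- rho * x[[t - 1]] + sqrt(1 - rho^2) * draw_cross_section(n, config)
  if (length(conf_idx) > 0 && lam > 0) {
    for (t in seq_len(tt))
      x[[t]][, conf_idx] <- sqrt(1 - lam^2) * x[[t]][, conf_idx] + lam * u
  }

  outcomes <- names(config$hazard_intercepts)
  causal_idx <- match(names(config$causal_coefs), config$predictor_names)
  lag2_idx <- match(names(config$lag2_coefs), config$predictor_names)
  hazard_eta <- function(o, t) {            # hazard logit for step index t >= 2
    eta <- rep(config$hazard_intercepts[[o]], n) +
      config$confounder_strength * u
    if (length(causal_idx) > 0)
      eta <- eta + drop(x[[t - 1]][, causal_idx, drop = FALSE] %*%
                          config$causal_coefs)
    if (length(lag2_idx) > 0 && t >= 3)
      eta <- eta + drop(x[[t - 2]][, lag2_idx, drop = FALSE] %*%
                          config$lag2_coefs)
    eta
  }
  y <- m <- list()
  for (o in outcomes) {
    ym <- matrix(0L, n, tt); mm <- matrix(1L, n, tt)
    at_risk <- rep(TRUE, n)
    for (t in seq_len(tt)[-1]) {
      ev <- at_risk & (stats::runif(n) < stats::plogis(hazard_eta(o, t)))
      ym[ev, t] <- 1L
      mm[!at_risk, t] <- 0L
      at_risk <- at_risk & !ev
    }
    if (tt > 1) {
      at_risk_rate <- sum(ym) / sum(mm[, -1])
      if (is.finite(at_risk_rate) && at_risk_rate >= 0.5)
        stop("outcome '", o, "': empirical per-interval event rate ",
             signif(at_risk_rate, 3), " >= 0.5; lower the hazard intercept")
    }
    y[[o]] <- ym; m[[o]] <- mm
  }
  list(x = x, u = u, y = y, m = m, hazard_eta = hazard_eta)
}

#' Simulate a longitudinal initiation panel with known causal structure
#'
#' Generates a tidy panel table (one row per subject and step) together with
#' the ground truth used to create it. Predictors are stationary AR(1) in
#' time with block-equicorrelated cross-sections; a standard-Gaussian
#' subject-level confounder, constant in time, loads on a predictor subset
#' and enters the hazard logit additively. For each outcome and each step
#' `t >= 1`, an at-risk subject initiates with probability
#' `plogis(intercept + sum(beta * X[t-1]) + c * U)`; true effects are
#' therefore lag-1 (plus optional lag-2 terms). Initiation is absorbing.
#' Missing values are injected completely at random into predictor cells.
#'
#' @param config a [sim_config()].
#' @return a list with components `panel` (a data.frame with columns
#'   `subject_id`, `step`, `y_<outcome>`, `m_<outcome>`, and predictors) and
#'   `truth` (a `sim_truth` object holding the generating mechanism).
#' @export
simulate_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  mech <- sim_mechanism(config)
  n <- config$n_subjects; tt <- config$n_steps; p <- config$n_predictors
  x <- mech$x; y <- mech$y; m <- mech$m
  outcomes <- names(config$hazard_intercepts)

  # assemble tidy table, one row per (subject, step)
  subj <- sprintf("S%05d", seq_len(n))
  panel <- data.frame(
    subject_id = rep(subj, each = tt),
    step = rep.int(seq_len(tt) - 1L, n),
    stringsAsFactors = FALSE
  )
  for (o in outcomes) {
    panel[[paste0("y_", o)]] <- as.integer(t(y[[o]]))
    panel[[paste0("m_", o)]] <- as.integer(t(m[[o]]))
  }
  pred <- matrix(NA_real_, n * tt, p, dimnames = list(NULL, config$predictor_names))
  for (t in seq_len(tt)) pred[seq(t, n * tt, by = tt), ] <- x[[t]]
  if (config$missing_rate > 0) {
    miss <- stats::runif(length(pred)) < config$missing_rate
    pred[miss] <- NA_real_
  }
  panel <- cbind(panel, as.data.frame(pred))

  edges <- if (length(config$causal_coefs) > 0 || length(config$lag2_coefs) > 0)
    do.call(rbind, c(
      lapply(outcomes, function(o) {
        rbind(
          if (length(config$causal_coefs) > 0)
            data.frame(predictor = names(config$causal_coefs), lag = 1L,
                       outcome = o, coef = unname(config$causal_coefs),
                       stringsAsFactors = FALSE),
          if (length(config$lag2_coefs) > 0)
            data.frame(predictor = names(config$lag2_coefs), lag = 2L,
                       outcome = o, coef = unname(config$lag2_coefs),
                       stringsAsFactors = FALSE)
        )
      })
    ))
  else data.frame(predictor = character(0), lag = integer(0),
                  outcome = character(0), coef = numeric(0))

  loadings <- stats::setNames(rep(0, p), config$predictor_names)
  loadings[confounded_indices(config)] <- config$confounder_loading
  truth <- structure(list(
    config = config, causal_edges = edges,
    confounder_loadings = loadings, seed = config$seed
  ), class = "sim_truth")
  list(panel = panel, truth = truth)
}

#' @export
print.sim_truth <- function(x, ...) {
  cat("Synthetic panel ground truth\n")
  cat("  subjects:", x$config$n_subjects, " steps:", x$config$n_steps,
      " predictors:", x$config$n_predictors, "\n")
  cat("  causal edges:", nrow(x$causal_edges), "\n")
  cat("  confounder strength:", x$config$confounder_strength, "\n")
  invisible(x)
}

#' Monte-Carlo oracle for the true adjusted effect of a lagged predictor
#'
#' Computes, by brute-force simulation from the generating mechanism, the
#' average change in per-interval initiation probability under a +1 SD
#' intervention on one lagged predictor, holding the latent confounder and
#' all other predictors at their generated values. The average is taken over
#' the at-risk rows (`m = 1`, `step >= lag`) of a freshly generated panel of
#' `n_mc` subjects, i.e. over the same survivor-selected population the
#' estimation stage analyses, so this is the probability-scale ground truth
#' for parameter-recovery and coverage tests.
#'
#' @param truth a `sim_truth` from [simulate_panel()].
#' @param predictor predictor name.
#' @param lag lag of the intervention (1, or 2 when lag-2 effects exist).
#' @param outcome outcome name.
#' @param n_mc number of Monte-Carlo subjects to simulate (>= 1e4); each
#'   contributes one draw per at-risk interval.
#' @param seed seed for the Monte-Carlo draw.
#' @return the oracle effect, a single number on the probability scale.
#' @export
true_effect_oracle <- function(truth, predictor, lag = 1L, outcome,
                               n_mc = 1e5, seed = 1L) {
  stopifnot(inherits(truth, "sim_truth"), n_mc >= 1e4)
  config <- truth$config
  if (!predictor %in% config$predictor_names)
    stop("unknown predictor: ", predictor)
  if (!outcome %in% names(config$hazard_intercepts))
    stop("unknown outcome: ", outcome)
  stopifnot(lag >= 1, lag < config$n_steps)
  mc_config <- config
  mc_config$n_subjects <- as.integer(n_mc)
  mc_config$seed <- as.integer(seed)
  mech <- sim_mechanism(mc_config)
  beta <- if (lag == 1L) unname(config$causal_coefs[predictor])
  else unname(config$lag2_coefs[predictor])
  if (is.na(beta) || is.null(beta)) beta <- 0
  num <- 0; den <- 0L
  for (t in seq_len(config$n_steps)[-seq_len(lag)]) {   # steps with lag history
    at_risk <- mech$m[[outcome]][, t] == 1L
    eta <- mech$hazard_eta(outcome, t)[at_risk]
    num <- num + sum(stats::plogis(eta + beta) - stats::plogis(eta))
    den <- den + sum(at_risk)
  }
  num / den
}

#' Write a panel and its ground truth to plain-text files
#'
#' The panel is written as CSV (empty cell = missing); the truth sidecar is a
#' small JSON file holding the generating coefficients and edges so test
#' harnesses can recover the mechanism without re-running the generator.
#'
#' @param sim the list returned by [simulate_panel()].
#' @param panel_path,truth_path output file paths.
#' @return invisibly, the two paths.
#' @export
write_sim <- function(sim, panel_path, truth_path) {
  write_panel(sim$panel, panel_path)
  truth <- sim$truth
  obj <- list(
    seed = truth$seed,
    n_subjects = truth$config$n_subjects, n_steps = truth$config$n_steps,
    hazard_intercepts = as.list(truth$config$hazard_intercepts),
    confounder_strength = truth$config$confounder_strength,
    confounder_loadings = as.list(truth$confounder_loadings[
      truth$confounder_loadings != 0]),
    causal_edges = truth$causal_edges
  )
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA), truth_path)
  invisible(c(panel_path, truth_path))
}
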