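#' Configuration for graph discovery
#'
#' Knobs for the first stage: class-weighted elastic-net logistic regression
#' on lagged features, with subject-level bootstrap stability selection.
#'
#' @param n_bootstrap number of bootstrap replicates (>= 2). 100 resolves
#'   stability scores to 0.01.
#' @param l1_ratio elastic-net mixing in (0, 1]; 0.5 balances sparsity with
#'   grouping of correlated predictors.
#' @param penalty_strength either a positive penalty value held fixed across
#'   replicates, or `"cv"` to choose it once on the full eligible data by
#'   subject-grouped cross-validated deviance (then held fixed — tuning per
#'   replicate would confound stability with tuning noise).
#' @param cv_rule which cross-validated penalty to take when
#'   `penalty_strength = "cv"`: `"1se"` (sparser, the stability-selection
#'   convention) or `"min"`.
#' @param class_weighting `"balanced"` weights classes inversely to their
#'   frequencies (rare initiation events would otherwise be ignored by the
#'   penalized fit); `"none"` disables it.
#' @param min_rows,prevalence_bounds eligibility thresholds, see
#'   [check_eligibility()].
#' @param max_lag lag order of the candidate predictor set.
#' @param deltas include `_D1` change features among candidates.
#' @param nonzero_tol coefficients with absolute value at or below this are
#'   treated as not selected (guards against solver round-off).
#' @param retry_cap redraws allowed when a bootstrap replicate's outcome is
#'   constant before erroring.
#' @param seed integer seed.
#' @return an object of class `discovery_config`.
#' @export
discovery_config <- function(n_bootstrap = 100L, l1_ratio = 0.5,
                             penalty_strength = "cv", cv_rule = c("1se", "min"),
                             class_weighting = c("balanced", "none"),
                             min_rows = 500L, prevalence_bounds = c(0.005, 0.995),
                             max_lag = 2L, deltas = FALSE,
                             nonzero_tol = 1e-8, retry_cap = 10L, seed = 1L) {
  cv_rule <- match.arg(cv_rule)
  class_weighting <- match.arg(class_weighting)
  stopifnot(n_bootstrap >= 2, l1_ratio > 0, l1_ratio <= 1,
            nonzero_tol >= 0, max_lag >= 1,
            prevalence_bounds[1] < prevalence_bounds[2])
  if (!identical(penalty_strength, "cv"))
    stopifnot(is.numeric(penalty_strength), penalty_strength > 0)
  structure(list(n_bootstrap = as.integer(n_bootstrap), l1_ratio = l1_ratio,
                 penalty_strength = penalty_strength, cv_rule = cv_rule,
                 class_weighting = class_weighting,
                 min_rows = as.integer(min_rows),
                 prevalence_bounds = prevalence_bounds,
                 max_lag = as.integer(max_lag), deltas = deltas,
                 nonzero_tol = nonzero_tol, retry_cap = as.integer(retry_cap),
                 seed = as.integer(seed)),
            class = "discovery_config")
}

# One subject-level bootstrap draw: sample subjects with replacement and
# return the row indices, where a subject drawn twice contributes all its
# rows twice. `row_of` is a list of row-index vectors, one per subject.
subject_bootstrap_indices <- function(row_of) {
  take <- sample(length(row_of), replace = TRUE)
  structure(unlist(row_of[take], use.names = FALSE), subjects = take)
}

balanced_weights <- function(y) {
  n <- length(y); tab <- table(factor(y, levels = c(0, 1)))
  w <- n / (2 * as.numeric(tab))
  unname(w[y + 1L])
}

#' Fit a class-weighted elastic-net logistic regression
#'
#' Fits the penalized logistic model predicting the interval-level outcome
#' from standardized lagged features. With balanced class weighting each
#' class contributes half the total weight, so rare initiation events are not
#' shrunk away purely by imbalance. Deterministic given data and config.
#'
#' @param x numeric feature matrix (already standardized; no missing values).
#' @param y binary 0/1 outcome vector.
#' @param config a [discovery_config()]; `penalty_strength` must be numeric
#'   here (use [choose_penalty()] first when it is `"cv"`).
#' @return list with `coef` (named vector over columns of `x`), `intercept`,
#'   and `lambda`.
#' @export
fit_sparse_model <- function(x, y, config) {
  stopifnot(nrow(x) == length(y))
  if (length(unique(y)) < 2) stop("outcome is constant; cannot fit")
  if (!is.numeric(config$penalty_strength))
    stop("penalty_strength is 'cv'; choose a penalty first with choose_penalty()")
  w <- if (config$class_weighting == "balanced") balanced_weights(y)
  else rep(1, length(y))
  padded <- ncol(x) == 1         # the solver requires >= 2 columns
  if (padded) x <- cbind(x, `.pad` = 0)
  lam <- config$penalty_strength
  # glmnet warm-starts down a path; append the target so the solution at
  # `lam` is well converged even when called with a single value
  path <- sort(unique(c(lam * c(8, 4, 2, 1))), decreasing = TRUE)
  fit <- glmnet::glmnet(x, y, family = "binomial", alpha = config$l1_ratio,
                        weights = w, lambda = path, standardize = FALSE,
                        thresh = 1e-9)
  cf <- as.numeric(stats::coef(fit, s = lam, exact = FALSE))
  coefs <- stats::setNames(cf[-1], colnames(x))
  if (padded) coefs <- coefs[-length(coefs)]
  list(coef = coefs, intercept = cf[1], lambda = lam)
}

#' Choose the elastic-net penalty by subject-grouped cross-validation
#'
#' Runs cross-validated deviance with folds that partition subjects (all of
#' a subject's rows share a fold, so repeated measures never leak across
#' folds) and returns the penalty under the configured rule. The chosen
#' value is then held fixed across every bootstrap replicate.
#'
#' @param x standardized feature matrix.
#' @param y binary outcome.
#' @param groups subject identifier per row.
#' @param config a [discovery_config()].
#' @param n_folds number of cross-validation folds.
#' @return the chosen penalty (a positive number).
#' @export
choose_penalty <- function(x, y, groups, config, n_folds = 5L) {
  subj <- unique(groups)
  fold_of <- stats::setNames(sample(rep_len(seq_len(n_folds), length(subj))),
                             subj)
  foldid <- as.integer(fold_of[as.character(groups)])
  w <- if (config$class_weighting == "balanced") balanced_weights(y)
  else rep(1, length(y))
  cv <- glmnet::cv.glmnet(x, y, family = "binomial", alpha = config$l1_ratio,
                          weights = w, foldid = foldid,
                          type.measure = "deviance", standardize = FALSE)
  if (config$cv_rule == "1se") cv$lambda.1se else cv$lambda.min
}

#' Bootstrap stability selection over subject-level resamples
#'
#' Scores every lagged predictor by the proportion of subject-level
#' bootstrap replicates in which the elastic net selects it. Each replicate
#' resamples subjects with replacement (a subject drawn twice contributes
#' all its rows twice), recomputes preprocessing statistics on the resampled
#' rows, and refits the model at the fixed penalty. A replicate whose
#' resampled outcome is constant is redrawn, up to `retry_cap` times.
#'
#' @param rows at-risk, eligibility-passed rows for one outcome, with lagged
#'   columns present.
#' @param outcome outcome name.
#' @param config a [discovery_config()].
#' @param columns candidate feature columns; default all `_L1.._Lmax_lag`
#'   (plus `_D1` when `deltas`) columns.
#' @return a `edge_candidates` data.frame: one row per predictor ever
#'   selected, with `predictor`, `outcome`, `stability`
#'   (= `selection_count / n_bootstrap`), `mean_coef` (mean standardized
#'   coefficient over the replicates where selected), `selection_count`,
#'   `n_bootstrap`; the chosen penalty is attached as attribute `"lambda"`.
#' @export
bootstrap_stability <- function(rows, outcome, config = discovery_config(),
                                columns = NULL) {
  if (is.null(columns))
    columns <- lagged_columns(rows, config$max_lag, config$deltas)
  if (length(columns) == 0) stop("no lagged candidate columns found")
  y_all <- rows[[paste0("y_", outcome)]]
  if (is.null(y_all)) stop("unknown outcome: ", outcome)
  groups <- rows$subject_id
  set.seed(config$seed)

  # penalty chosen once on the full eligible data, then held fixed
  lam <- config$penalty_strength
  if (identical(lam, "cv")) {
    fm_full <- preprocess(rows, columns)
    lam <- choose_penalty(fm_full$x, y_all, groups, config)
  }
  cfg_fixed <- config; cfg_fixed$penalty_strength <- lam

  subj <- unique(groups)
  row_of <- split(seq_len(nrow(rows)), factor(groups, levels = subj))
  sel_count <- stats::setNames(integer(length(columns)), columns)
  coef_sum <- stats::setNames(numeric(length(columns)), columns)

  for (b in seq_len(config$n_bootstrap)) {
    for (try in seq_len(config$retry_cap + 1L)) {
      idx <- subject_bootstrap_indices(row_of)
      # a replicate needs both classes represented (>= 2 rows each) to fit
      if (min(tabulate(y_all[idx] + 1L, 2L)) >= 2L) break
      if (try > config$retry_cap)
        stop("bootstrap replicate for outcome '", outcome,
             "' had a degenerate resampled outcome ", config$retry_cap,
             " times; outcome too rare for stability selection")
    }
    fm <- preprocess(rows[idx, , drop = FALSE], columns)
    fit <- fit_sparse_model(fm$x, y_all[idx], cfg_fixed)
    sel <- abs(fit$coef) > config$nonzero_tol
    sel_count[sel] <- sel_count[sel] + 1L
    coef_sum[sel] <- coef_sum[sel] + fit$coef[sel]
  }

  keep <- sel_count > 0
  out <- data.frame(predictor = columns[keep], outcome = outcome,
                    stability = unname(sel_count[keep]) / config$n_bootstrap,
                    mean_coef = unname(coef_sum[keep] / sel_count[keep]),
                    selection_count = unname(sel_count[keep]),
                    n_bootstrap = config$n_bootstrap,
                    stringsAsFactors = FALSE)
  out <- rank_edges(out)
  attr(out, "lambda") <- lam
  class(out) <- c("edge_candidates", "data.frame")
  out
}

#' Rank candidate edges
#'
#' Sorts by stability (descending), breaking ties by absolute mean
#' coefficient (descending) and then predictor name (ascending).
#'
#' @param candidates an edge-candidate data.frame.
#' @param top_k optionally truncate to the best `top_k` rows.
#' @return the sorted (possibly truncated) data.frame.
#' @export
rank_edges <- function(candidates, top_k = NULL) {
  ord <- order(-candidates$stability, -abs(candidates$mean_coef),
               candidates$predictor)
  out <- candidates[ord, , drop = FALSE]
  if (!is.null(top_k)) out <- utils::head(out, top_k)
  rownames(out) <- NULL
  out
}

#' Write ranked edges to a delimited file
#'
#' @param candidates an edge-candidate data.frame.
#' @param path output path (CSV).
#' @param top_k optional truncation.
#' @return the path, invisibly.
#' @export
export_edges <- function(candidates, path, top_k = NULL) {
  out <- rank_edges(candidates, top_k)
  utils::write.table(out, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an edges table written by [export_edges()]
#' @param path CSV path.
#' @return an edge-candidate data.frame.
#' @export
read_edges <- function(path) {
  out <- utils::read.table(path, header = TRUE, sep = ",",
                           stringsAsFactors = FALSE)
  class(out) <- c("edge_candidates", "data.frame")
  out
}
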