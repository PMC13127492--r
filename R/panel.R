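#' Read or write a longitudinal panel as delimited text
#'
#' Panels are tidy tables with one row per (subject, step): a `subject_id`
#' column, an integer `step` column, per-outcome `y_*`/`m_*` indicator
#' columns, and predictor columns. The delimiter is chosen by extension:
#' `.tsv`/`.txt` is tab-separated, anything else comma-separated. Empty cells
#' are missing values.
#'
#' @param path file path.
#' @param panel a panel data.frame.
#' @return `read_panel` returns a data.frame; `write_panel` returns the path,
#'   invisibly.
#' @export
read_panel <- function(path) {
  sep <- if (grepl("\\.(tsv|txt)$", path)) "\t" else ","
  panel <- utils::read.table(path, header = TRUE, sep = sep,
                             stringsAsFactors = FALSE, check.names = FALSE,
                             na.strings = c("", "NA"))
  if (!all(c("subject_id", "step") %in% names(panel)))
    stop("panel file must have 'subject_id' and 'step' columns")
  panel$step <- as.integer(panel$step)
  panel
}

#' @rdname read_panel
#' @export
write_panel <- function(panel, path) {
  sep <- if (grepl("\\.(tsv|txt)$", path)) "\t" else ","
  utils::write.table(panel, path, sep = sep, row.names = FALSE,
                     quote = FALSE, na = "")
  invisible(path)
}

#' Check the structural invariants of a panel table
#'
#' Verifies that (subject, step) pairs are unique, steps are contiguous from
#' 0 within each subject, and for every outcome the at-risk indicator is
#' consistent with absorbing initiation: `m = 1` on every row up to and
#' including the first `y = 1`, `m = 0` strictly after, and `y = 1` only
#' where `m = 1`.
#'
#' @param panel a panel data.frame.
#' @return `TRUE`, invisibly; stops with a message on violation.
#' @export
validate_panel <- function(panel) {
  key <- paste(panel$subject_id, panel$step)
  if (anyDuplicated(key)) stop("duplicate (subject_id, step) rows")
  ord <- order(panel$subject_id, panel$step)
  sp <- split(panel$step[ord], panel$subject_id[ord])
  bad <- !vapply(sp, function(s) identical(as.integer(s),
                                           seq_len(length(s)) - 1L), logical(1))
  if (any(bad)) stop("steps not contiguous from 0 for subject(s): ",
                     paste(utils::head(names(sp)[bad], 3), collapse = ", "))
  for (o in panel_outcomes(panel)) {
    y <- panel[[paste0("y_", o)]][ord]; m <- panel[[paste0("m_", o)]][ord]
    if (any(y == 1 & m == 0)) stop("y_", o, " = 1 on a row with m_", o, " = 0")
    for (s in split(seq_along(y), panel$subject_id[ord])) {
      first <- match(1L, y[s])
      expect_m <- if (is.na(first)) rep(1L, length(s))
      else c(rep(1L, first), rep(0L, length(s) - first))
      if (!identical(as.integer(m[s]), expect_m))
        stop("at-risk indicator m_", o, " inconsistent with absorbing ",
             "initiation for a subject")
    }
  }
  invisible(TRUE)
}

#' Outcome names present in a panel
#'
#' Outcomes are the names `o` for which both `y_o` and `m_o` columns exist.
#' @param panel a panel data.frame.
#' @return character vector of outcome names.
#' @export
panel_outcomes <- function(panel) {
  y <- sub("^y_", "", grep("^y_", names(panel), value = TRUE))
  m <- sub("^m_", "", grep("^m_", names(panel), value = TRUE))
  intersect(y, m)
}

#' Predictor columns of a panel
#'
#' Everything that is not an identifier, step, outcome, at-risk, lagged
#' (`_L<k>`) or delta (`_D1`) column.
#' @param panel a panel data.frame.
#' @return character vector of raw predictor column names.
#' @export
panel_predictors <- function(panel) {
  nm <- setdiff(names(panel), c("subject_id", "step"))
  nm <- nm[!grepl("^(y|m)_", nm)]
  nm[!grepl("_L[0-9]+$|_D1$", nm)]
}

#' Lag specification
#'
#' @param max_lag largest lag order `k`; lagged columns use the `_L<k>`
#'   suffix convention (`_L1` = previous interval).
#' @param deltas whether change scores `p_D1 = p_L1 - p_L2` are also built
#'   (requires `max_lag >= 2`).
#' @return an object of class `lag_spec`.
#' @export
lag_spec <- function(max_lag = 2L, deltas = FALSE) {
  stopifnot(max_lag >= 1)
  if (deltas && max_lag < 2) stop("delta features require max_lag >= 2")
  structure(list(max_lag = as.integer(max_lag), deltas = deltas),
            class = "lag_spec")
}

#' Add lagged predictor columns with leak-free temporal ordering
#'
#' For every raw predictor `p` and each lag `k` in `1..max_lag`, adds a
#' column `p_Lk` holding the subject's own value of `p` at step `t - k`
#' (missing when no such step exists). Lags never cross subjects and depend
#' only on (subject, step), never on row order. Downstream models consume
#' only these lagged columns, so predictors always temporally precede the
#' outcome.
#'
#' @param panel a panel data.frame.
#' @param spec a [lag_spec()].
#' @return the panel with lagged (and, if requested, delta) columns appended.
#' @export
build_lagged_features <- function(panel, spec = lag_spec()) {
  preds <- panel_predictors(panel)
  if (length(preds) == 0) stop("panel has no predictor columns")
  key <- paste(panel$subject_id, panel$step, sep = "\r")
  if (anyDuplicated(key)) stop("duplicate (subject_id, step) rows")
  for (k in seq_len(spec$max_lag)) {
    idx <- match(paste(panel$subject_id, panel$step - k, sep = "\r"), key)
    for (p in preds) {
      nm <- paste0(p, "_L", k)
      if (nm %in% names(panel))
        stop("column '", nm, "' already exists; refusing to overwrite")
      panel[[nm]] <- panel[[p]][idx]
    }
  }
  if (isTRUE(spec$deltas)) panel <- build_delta_features(panel, spec)
  panel
}

#' Add change (delta) features from already-lagged columns
#'
#' `p_D1 = p_L1 - p_L2`: the change in `p` over the interval before the
#' current one. Both operands are lagged, so the delta is fully in the past;
#' it is missing whenever either operand is.
#'
#' @inheritParams build_lagged_features
#' @export
build_delta_features <- function(panel, spec = lag_spec(max_lag = 2L)) {
  if (spec$max_lag < 2) stop("delta features require max_lag >= 2")
  for (p in panel_predictors(panel)) {
    l1 <- paste0(p, "_L1"); l2 <- paste0(p, "_L2")
    if (!all(c(l1, l2) %in% names(panel)))
      stop("lagged columns missing for '", p, "'; run build_lagged_features first")
    panel[[paste0(p, "_D1")]] <- panel[[l1]] - panel[[l2]]
  }
  panel
}

#' Names of the lagged feature columns used as model inputs
#'
#' @param panel a panel data.frame with lagged columns.
#' @param max_lag largest lag suffix to include.
#' @param deltas include `_D1` change columns.
#' @return character vector of lagged (and delta) column names.
#' @export
lagged_columns <- function(panel, max_lag = 2L, deltas = FALSE) {
  pat <- paste0("_L[1-", max_lag, "]$")
  out <- grep(pat, names(panel), value = TRUE)
  if (deltas) out <- c(out, grep("_D1$", names(panel), value = TRUE))
  out
}

#' Select the at-risk estimation rows for one outcome
#'
#' Keeps exactly the rows where the subject is still at risk for the outcome
#' (`m_<outcome> = 1`) and at least one prior interval is available
#' (`step >= 1`). Rows after a subject's initiation are excluded by the
#' absorbing at-risk indicator; the first interval is excluded because it has
#' no lagged history.
#'
#' @param panel a panel data.frame.
#' @param outcome outcome name (without the `y_`/`m_` prefix).
#' @return the subset of rows, same columns.
#' @export
select_at_risk_rows <- function(panel, outcome) {
  m <- paste0("m_", outcome)
  if (!m %in% names(panel)) stop("unknown outcome: ", outcome)
  panel[panel[[m]] == 1 & panel$step >= 1, , drop = FALSE]
}

#' Screen an outcome for eligibility
#'
#' An outcome is analysed only when its at-risk rows are numerous enough,
#' the event prevalence is neither extreme nor degenerate, and the outcome
#' varies. The report lists every reason that failed.
#'
#' @param rows at-risk-filtered rows (from [select_at_risk_rows()]).
#' @param outcome outcome name.
#' @param min_rows minimum number of eligible rows (default 500).
#' @param prevalence_bounds length-2 numeric `(low, high)` on event
#'   prevalence among eligible rows.
#' @return an `eligibility_report` list: `outcome`, `n_rows`, `prevalence`,
#'   `passed`, `failure_reasons`.
#' @export
check_eligibility <- function(rows, outcome, min_rows = 500L,
                              prevalence_bounds = c(0.005, 0.995)) {
  stopifnot(length(prevalence_bounds) == 2,
            prevalence_bounds[1] < prevalence_bounds[2])
  y <- rows[[paste0("y_", outcome)]]
  n <- length(y)
  prev <- if (n > 0) mean(y) else NA_real_
  reasons <- character(0)
  if (n < min_rows) reasons <- c(reasons, "too_few_rows")
  if (n > 0 && prev < prevalence_bounds[1]) reasons <- c(reasons, "prevalence_low")
  if (n > 0 && prev > prevalence_bounds[2]) reasons <- c(reasons, "prevalence_high")
  if (n == 0 || length(unique(y)) < 2) reasons <- c(reasons, "no_variation")
  structure(list(outcome = outcome, n_rows = n, prevalence = prev,
                 passed = length(reasons) == 0, failure_reasons = reasons),
            class = "eligibility_report")
}

#' @export
print.eligibility_report <- function(x, ...) {
  cat("Eligibility for outcome '", x$outcome, "': ",
      if (x$passed) "PASSED" else "FAILED", "\n", sep = "")
  cat("  rows:", x$n_rows, " prevalence:", signif(x$prevalence, 4), "\n")
  if (!x$passed) cat("  reasons:", paste(x$failure_reasons, collapse = ", "), "\n")
  invisible(x)
}

#' Preprocess feature columns into a clean standardized matrix
#'
#' Coerces each requested column to numeric (uncoercible entries become
#' missing), treats non-finite values as missing, imputes each column's
#' missing entries with the column median of observed values (fallback 0 when
#' nothing is observed), then z-scores. Constant columns become all-zero.
#' The per-column medians, means and SDs are stored so the identical
#' transform can be replayed on held-out rows with [apply_preprocess()].
#'
#' @param rows a data.frame holding the fitting rows.
#' @param columns names of the feature columns to use.
#' @return a `feature_matrix`: list with `x` (numeric matrix, rows aligned to
#'   `rows`), `columns`, `medians`, `means`, `sds`.
#' @export
preprocess <- function(rows, columns) {
  if (length(columns) == 0) stop("no feature columns requested")
  missing_cols <- setdiff(columns, names(rows))
  if (length(missing_cols) > 0)
    stop("columns not in data: ", paste(utils::head(missing_cols, 3), collapse = ", "))
  x <- matrix(NA_real_, nrow(rows), length(columns),
              dimnames = list(NULL, columns))
  for (j in seq_along(columns))
    x[, j] <- suppressWarnings(as.numeric(rows[[columns[j]]]))
  x[!is.finite(x)] <- NA_real_
  med <- apply(x, 2, function(v) {
    m <- stats::median(v, na.rm = TRUE)
    if (is.na(m)) 0 else m
  })
  for (j in seq_along(columns)) {
    v <- x[, j]; v[is.na(v)] <- med[j]; x[, j] <- v
  }
  mu <- colMeans(x)
  sd <- apply(x, 2, stats::sd)
  sd[!is.finite(sd) | sd == 0] <- NA_real_   # constant column marker
  for (j in seq_along(columns))
    x[, j] <- if (is.na(sd[j])) 0 else (x[, j] - mu[j]) / sd[j]
  structure(list(x = x, columns = columns, medians = med, means = mu, sds = sd),
            class = "feature_matrix")
}

#' Replay a stored preprocessing transform on new rows
#'
#' Applies the medians/means/SDs learned by [preprocess()] on the fitting
#' rows to held-out rows, so train and test share the same feature space.
#'
#' @param fm a `feature_matrix`.
#' @param rows new data.frame containing the same columns.
#' @return a numeric matrix with the same columns as `fm$x`.
#' @export
apply_preprocess <- function(fm, rows) {
  stopifnot(inherits(fm, "feature_matrix"))
  x <- matrix(NA_real_, nrow(rows), length(fm$columns),
              dimnames = list(NULL, fm$columns))
  for (j in seq_along(fm$columns))
    x[, j] <- suppressWarnings(as.numeric(rows[[fm$columns[j]]]))
  x[!is.finite(x)] <- NA_real_
  for (j in seq_along(fm$columns)) {
    v <- x[, j]; v[is.na(v)] <- fm$medians[j]
    x[, j] <- if (is.na(fm$sds[j])) 0 else (v - fm$means[j]) / fm$sds[j]
  }
  x
}

#' Cohort initiation summary
#'
#' Counts, per outcome, the subjects that ever initiated (any row with
#' `y = 1`) and reports the percentage of the cohort, rounded to three
#' significant figures as such cohort tables conventionally print.
#'
#' @param panel a panel data.frame.
#' @param outcomes outcome names; default all outcomes present.
#' @return data.frame with `outcome`, `n_initiators`, `n_total`, `percent`.
#' @export
cohort_summary <- function(panel, outcomes = panel_outcomes(panel)) {
  n_total <- length(unique(panel$subject_id))
  rows <- lapply(outcomes, function(o) {
    y <- panel[[paste0("y_", o)]]
    init <- unique(panel$subject_id[y == 1])
    data.frame(outcome = o, n_initiators = length(init), n_total = n_total,
               percent = initiation_percent(length(init), n_total),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Initiation percentage at reported precision
#'
#' `100 * n_initiators / n_total`, rounded to three significant figures —
#' the precision at which cohort tables print such proportions.
#'
#' @param n_initiators,n_total counts.
#' @return a number (e.g. 36.5 for 4330/11868).
#' @export
initiation_percent <- function(n_initiators, n_total) {
  if (n_total == 0) return(NA_real_)
  signif(100 * n_initiators / n_total, 3)
}
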