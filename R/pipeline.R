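#' End-to-end run configuration
#'
#' Bundles the stage configurations and I/O for [run_pipeline()]. Exactly one
#' of `panel_path` (read an existing panel) or `sim` (generate one) must be
#' given. Shared fields are kept consistent: the lag spec's `max_lag` is
#' propagated to both stage configs.
#'
#' @param panel_path path to a delimited panel file, or `NULL`.
#' @param sim a [sim_config()], or `NULL`.
#' @param outcomes outcome names to analyse; default all present.
#' @param lag a [lag_spec()].
#' @param discovery a [discovery_config()].
#' @param effects an [effect_config()].
#' @param out_dir directory for result tables; `NULL` writes nothing.
#' @param seed master seed, propagated to every stage config.
#' @return an object of class `run_config`.
#' @export
run_config <- function(panel_path = NULL, sim = NULL, outcomes = NULL,
                       lag = lag_spec(), discovery = discovery_config(),
                       effects = effect_config(), out_dir = NULL, seed = 1L) {
  if (is.null(panel_path) == is.null(sim))
    stop("give exactly one of panel_path or sim")
  discovery$max_lag <- lag$max_lag; discovery$deltas <- lag$deltas
  effects$max_lag <- lag$max_lag; effects$deltas <- lag$deltas
  discovery$seed <- as.integer(seed); effects$seed <- as.integer(seed)
  structure(list(panel_path = panel_path, sim = sim, outcomes = outcomes,
                 lag = lag, discovery = discovery, effects = effects,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full two-stage pipeline
#'
#' Simulates or reads a panel, builds lagged features, and for each outcome:
#' selects at-risk rows, screens eligibility, runs bootstrap stability
#' selection, keeps the stable edges, and estimates their adjusted effects
#' on the estimation split. Ineligible outcomes are skipped with logged
#' reasons. Identical configuration and seed give identical result tables.
#'
#' @param config a [run_config()].
#' @param quiet suppress progress messages.
#' @return a `run_report` list: `eligibility` (per-outcome reports), `edges`
#'   (all candidates), `stable_edges`, `effects`, `summary` (per-outcome
#'   counts), and `fingerprint` (package version + seed + key settings).
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (!quiet) message(...)
  panel <- if (!is.null(config$sim)) {
    say("simulating panel (", config$sim$n_subjects, " subjects x ",
        config$sim$n_steps, " steps)")
    simulate_panel(config$sim)$panel
  } else {
    say("reading panel from ", config$panel_path)
    read_panel(config$panel_path)
  }
  panel <- build_lagged_features(panel, config$lag)
  outcomes <- config$outcomes %||% panel_outcomes(panel)

  elig <- list(); edges <- list(); effects <- list()
  for (o in outcomes) {
    rows <- select_at_risk_rows(panel, o)
    rep <- check_eligibility(rows, o, config$discovery$min_rows,
                             config$discovery$prevalence_bounds)
    elig[[o]] <- rep
    if (!rep$passed) {
      say("outcome '", o, "' skipped: ",
          paste(rep$failure_reasons, collapse = ", "))
      next
    }
    say("outcome '", o, "': ", rep$n_rows, " eligible rows, prevalence ",
        signif(rep$prevalence, 3), "; running stability selection")
    cand <- bootstrap_stability(rows, o, config$discovery)
    edges[[o]] <- cand
    stable <- select_stable_edges(cand, config$effects)
    if (nrow(stable) == 0) {
      say("outcome '", o, "': no edge reached stability ",
          config$effects$stability_threshold)
      next
    }
    split <- make_estimation_split(panel, config$effects)
    effects[[o]] <- estimate_effects(split$estimation, stable, config$effects,
                                     config$discovery$min_rows,
                                     config$discovery$prevalence_bounds)
  }

  all_edges <- if (length(edges) > 0) do.call(rbind, unname(edges))
  else data.frame()
  stable_edges <- if (nrow(all_edges) > 0)
    select_stable_edges(all_edges, config$effects) else all_edges
  all_effects <- if (length(effects) > 0) do.call(rbind, unname(effects))
  else data.frame()
  rownames(all_effects) <- NULL

  report <- structure(list(
    eligibility = elig, edges = all_edges, stable_edges = stable_edges,
    effects = all_effects,
    summary = data.frame(
      outcome = outcomes,
      eligible = vapply(outcomes, function(o) elig[[o]]$passed, logical(1)),
      n_candidates = vapply(outcomes, function(o) {
        if (is.null(edges[[o]])) 0L else nrow(edges[[o]])
      }, integer(1)),
      n_stable = vapply(outcomes, function(o) {
        if (nrow(stable_edges) == 0) 0L
        else sum(stable_edges$outcome == o)
      }, integer(1)),
      n_estimated = vapply(outcomes, function(o) {
        if (is.null(effects[[o]])) 0L else nrow(effects[[o]])
      }, integer(1)),
      stringsAsFactors = FALSE),
    fingerprint = list(
      package = as.character(utils::packageVersion("lagdml")),
      seed = config$seed, max_lag = config$lag$max_lag,
      n_bootstrap = config$discovery$n_bootstrap,
      stability_threshold = config$effects$stability_threshold,
      nuisance_learner = config$effects$nuisance_learner)
  ), class = "run_report")

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    if (nrow(all_edges) > 0)
      export_edges(all_edges, file.path(config$out_dir, "edges.csv"))
    utils::write.table(all_effects, file.path(config$out_dir, "effects.csv"),
                       sep = ",", row.names = FALSE, quote = FALSE)
    writeLines(jsonlite::toJSON(report$fingerprint, auto_unbox = TRUE),
               file.path(config$out_dir, "run_fingerprint.json"))
  }
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("Two-stage discovery + effect-estimation run\n")
  print(x$summary, row.names = FALSE)
  if (nrow(x$effects) > 0) {
    cat("\nEstimated effects (theta per 1 SD of treatment):\n")
    print(render_summaries(x$stable_edges, x$effects)$effects,
          row.names = FALSE)
  }
  invisible(x)
}

#' Human-readable summary tables
#'
#' Per-outcome top-k stability table and the effects table with confidence
#' intervals, in the [rank_edges()] ordering.
#'
#' @param edges edge candidates.
#' @param effects effects table.
#' @param top_k rows per outcome in the stability table.
#' @return list of two data.frames, `stability` and `effects`.
#' @export
render_summaries <- function(edges, effects, top_k = 10L) {
  stab <- if (is.null(edges) || nrow(edges) == 0)
    data.frame(predictor = character(0), outcome = character(0),
               stability = numeric(0), mean_coef = numeric(0))
  else {
    parts <- lapply(split(edges, edges$outcome), rank_edges, top_k = top_k)
    out <- do.call(rbind, parts)[, c("predictor", "outcome", "stability",
                                     "mean_coef")]
    rownames(out) <- NULL
    out$mean_coef <- signif(out$mean_coef, 3)
    out
  }
  eff <- if (is.null(effects) || nrow(effects) == 0)
    data.frame(predictor = character(0), outcome = character(0),
               theta = numeric(0), ci = character(0))
  else data.frame(predictor = effects$predictor, outcome = effects$outcome,
                  theta = signif(effects$theta, 3),
                  ci = sprintf("[%s, %s]", signif(effects$ci_low, 3),
                               signif(effects$ci_high, 3)),
                  stability = effects$stability,
                  stringsAsFactors = FALSE)
  list(stability = stab, effects = eff)
}
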