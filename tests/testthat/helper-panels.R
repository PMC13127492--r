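# Hand-built panels and small simulation configs shared across test files.

# A tiny panel built by hand: 3 subjects x 3 steps, one outcome "use".
# Subject A initiates at step 1, B never initiates, C initiates at step 2.
tiny_panel <- function() {
  data.frame(
    subject_id = rep(c("A", "B", "C"), each = 3),
    step = rep(0:2, 3),
    y_use = c(0, 1, 0, 0, 0, 0, 0, 0, 1),
    m_use = c(1, 1, 0, 1, 1, 1, 1, 1, 1),
    p = c(3, 7, 9, 1, 1, 1, 2, 4, 8),
    q = c(0.5, 0.2, -1, 0, 0, 0, 10, 20, 30),
    stringsAsFactors = FALSE
  )
}

# Small fast simulation: a few hundred subjects, few predictors.
small_sim_config <- function(seed = 1, ...) {
  args <- list(n_subjects = 300L, n_steps = 4L, n_predictors = 6L,
               n_causal = 2L, causal_coefs = c(pred_001 = 0.8, pred_002 = -0.6),
               hazard_intercepts = c(use = stats::qlogis(0.08)),
               confounder_strength = 0.3, missing_rate = 0.05, seed = seed)
  args[names(list(...))] <- list(...)
  do.call(sim_config, args)
}

# Random residual-regression inputs with a cluster structure, for the
# sandwich and closed-form checks.
random_cluster_data <- function(n_clusters, rows_per_cluster, seed) {
  set.seed(seed)
  g <- rep(seq_len(n_clusters), each = rows_per_cluster)
  n <- length(g)
  list(d = stats::rnorm(n), y = stats::rnorm(n), groups = paste0("s", g))
}
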