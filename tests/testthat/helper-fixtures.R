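# Shared fixtures, built in code.

# a small but valid design: 4 sessions x 3 pages x 11 items
tiny_design <- function(n_sessions = 4) {
  experiment_design(n_sessions = n_sessions, n_practice_sessions = 1)
}

# simple no-variability parameter set used in several fitting tests
simple_params <- function() {
  diffusion_params(v_word = 1.5, v_nonword = -1.8, a = 1.6,
                   zr_word = 0.6, zr_nonword = 0.45, t0 = 0.3)
}

# zero between-person spread: every participant equals the profile mean
zero_sds <- function() {
  stats::setNames(rep(0, 9),
                  c("v_word", "v_nonword", "a", "zr_word", "zr_nonword",
                    "t0", "s_v", "s_zr", "s_t0"))
}

# bare trial table from simulated responses (no stroke bookkeeping)
sim_trials <- function(params, n_per_cond, id = "p1", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rows <- lapply(c("word", "nonword"), function(cond) {
    sim <- simulate_trials(n_per_cond, params, cond)
    data.frame(participant_id = id, session = 1L, page = 1L,
               slot = seq_len(n_per_cond) + 1L, condition = cond,
               is_reference = FALSE, is_practice = FALSE,
               response = ifelse(sim$response == "upper", "word", "nonword"),
               rt = sim$rt, stringsAsFactors = FALSE)
  })
  tr <- do.call(rbind, rows)
  tr$correct <- tr$response == tr$condition
  tr
}

# a fast fit configuration for smoke tests
quick_config <- function(n_restarts = 2, max_iterations = 300, ...) {
  fit_config(fix_variabilities_at_zero = TRUE, n_restarts = n_restarts,
             max_iterations = max_iterations, ...)
}

# one cached converged fit on simple simulated data, reused across tests
cached_simple_fit <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      tr <- sim_trials(simple_params(), 800, seed = 421)
      tr <- trim_rts(tr)$trials
      cache <<- list(fit = fit_participant(tr, quick_config(), seed = 422),
                     trials = tr)
    }
    cache
  }
})

# long-format data for mixed ANOVA tests
anova_fixture <- function() {
  data.frame(subject = rep(c("a1", "a2", "b1", "b2"), each = 2),
             group = rep(c("A", "A", "B", "B"), each = 2),
             condition = rep(c("c1", "c2"), 4),
             value = c(1, 3, 3, 4, 2, 6, 4, 8),
             stringsAsFactors = FALSE)
}

random_anova_data <- function(n_per_group) {
  n <- 2 * n_per_group
  data.frame(subject = rep(sprintf("s%02d", 1:n), each = 2),
             group = rep(c("A", "B"), each = 2 * n_per_group),
             condition = rep(c("c1", "c2"), n),
             value = rnorm(2 * n),
             stringsAsFactors = FALSE)
}
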