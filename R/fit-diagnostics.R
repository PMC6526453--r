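#' Model-level goodness-of-fit p-value
#'
#' One p-value per fitted participant model: the minimum of the word and
#' nonword KS p-values (conservative and monotone in both).
#'
#' @param fit A `fit_result` or a per-participant fit table with columns
#'   `ks_p_word` and `ks_p_nonword`.
#' @return A p-value (or vector of p-values for a fit table).
#' @export
model_p <- function(fit) {
  if (inherits(fit, "fit_result"))
    return(min(fit$ks_p_word, fit$ks_p_nonword))
  pmin(fit$ks_p_word, fit$ks_p_nonword)
}

#' Calibrate the goodness-of-fit criterion by parametric bootstrap
#'
#' The KS test rejects well-fitting diffusion models too often when trial
#' numbers are large, so the nominal cutoff is replaced by a simulation
#' calibrated one: parameter vectors are drawn from a multivariate normal
#' with the mean and covariance of the fitted cohort parameters (redrawn
#' until the invariants hold), a dataset of empirically resampled trial
#' counts is simulated from each and refitted with the same configuration,
#' and the critical value is the `alpha` quantile of the resulting model
#' p-values.
#'
#' @param fits Per-participant fit table ([fit_cohort()]).
#' @param config The [fit_config()] used for the original fits.
#' @param n_sims Number of simulated datasets (>= 1).
#' @param alpha Nominal level of the fit criterion.
#' @param trim_lo,trim_hi RT trimming window applied to simulated data.
#' @param seed Optional seed.
#' @param dt Euler step for the simulator.
#' @param verbose Progress output.
#' @return An object of class `calibration_result`: `critical_p`,
#'   `simulated_p`, `alpha`, `n_sims`.
#' @export
bootstrap_critical_p <- function(fits, config = fit_config(), n_sims = 1000,
                                 alpha = 0.01, trim_lo = 0.25, trim_hi = 3.5,
                                 seed = NULL, dt = 2e-4, verbose = FALSE) {
  if (n_sims < 1) stop("n_sims must be at least 1")
  ok <- fits$converged & !is.na(fits$v_word)
  if (sum(ok) < 2) stop("need at least two converged fits")
  if (!is.null(seed)) set.seed(seed)
  nm <- c("v_word", "v_nonword", "a", "zr_word", "zr_nonword",
          "t0", "s_v", "s_zr", "s_t0")
  X <- as.matrix(fits[ok, nm])
  mu <- colMeans(X)
  S <- stats::var(X)
  R <- tryCatch(chol(S), error = function(e) NULL)
  if (is.null(R)) {
    warning("singular parameter covariance; falling back to diagonal")
    R <- diag(sqrt(diag(S)), nrow = length(mu))
  }
  counts <- fits[ok, c("n_word", "n_nonword")]

  sim_p <- numeric(n_sims)
  for (b in seq_len(n_sims)) {
    p <- draw_mvn_params(mu, R, nm)
    cnt <- counts[sample(nrow(counts), 1), ]
    trials <- simulate_participant_trials(p, cnt$n_word, cnt$n_nonword, dt)
    trials <- trim_rts(trials, trim_lo, trim_hi)$trials
    fit <- fit_participant(trials, config)
    sim_p[b] <- model_p(fit)
    if (verbose && b %% 10 == 0)
      cat(sprintf("bootstrap %d/%d (p = %.4f)\n", b, n_sims, sim_p[b]))
  }
  structure(list(critical_p = unname(stats::quantile(sim_p, alpha, type = 1,
                                                     na.rm = TRUE)),
                 simulated_p = sim_p, alpha = alpha, n_sims = n_sims),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("Bootstrap fit calibration: critical p = %.4f (alpha = %g, %d sims)\n",
              x$critical_p, x$alpha, x$n_sims))
  invisible(x)
}

draw_mvn_params <- function(mu, R, nm, tries = 1000) {
  for (i in seq_len(tries)) {
    th <- as.numeric(mu + crossprod(R, stats::rnorm(length(mu))))
    names(th) <- nm
    th[c("s_v", "s_zr", "s_t0")] <- pmax(th[c("s_v", "s_zr", "s_t0")], 0)
    p <- tryCatch(do.call(diffusion_params, as.list(th)),
                  error = function(e) NULL)
    if (!is.null(p)) return(p)
  }
  stop("could not draw a feasible parameter vector from the bootstrap MVN")
}

## bare in-memory trial table for a simulated participant
simulate_participant_trials <- function(params, n_word, n_nonword, dt = 2e-4) {
  rows <- lapply(c(word = "word", nonword = "nonword"), function(cond) {
    n <- if (cond == "word") n_word else n_nonword
    sim <- simulate_trials(n, params, cond, dt = dt)
    data.frame(participant_id = "sim", session = 1L, page = 1L,
               slot = seq_len(n) + 1L, condition = cond,
               is_reference = FALSE, is_practice = FALSE,
               response = ifelse(sim$response == "upper", "word", "nonword"),
               rt = sim$rt, stringsAsFactors = FALSE)
  })
  tr <- do.call(rbind, rows)
  tr$correct <- tr$response == tr$condition
  rownames(tr) <- NULL
  tr
}

#' Flag poorly fitting participant models
#'
#' @param fits Per-participant fit table.
#' @param critical_p Calibrated criterion (e.g. from
#'   [bootstrap_critical_p()]).
#' @return A data frame with `participant_id`, `model_p` and `flagged`
#'   (`model_p < critical_p`); the number flagged is attached as attribute
#'   `n_flagged`.
#' @export
flag_misfit <- function(fits, critical_p) {
  stopifnot(critical_p >= 0, critical_p <= 1)
  mp <- model_p(fits)
  out <- data.frame(participant_id = fits$participant_id, model_p = mp,
                    flagged = mp < critical_p, stringsAsFactors = FALSE)
  attr(out, "n_flagged") <- sum(out$flagged, na.rm = TRUE)
  out
}

#' Empirical vs predicted CDF overlay
#'
#' Exports the curves behind a fit-quality plot: the empirical signed-RT
#' step function of one condition against the fitted model's predicted
#' signed CDF, evaluated on a common grid.
#'
#' @param fit A converged `fit_result`.
#' @param trials The participant's trimmed trials.
#' @param condition `"word"` or `"nonword"`.
#' @param grid Signed-time grid; defaults to the sample points.
#' @param trim_lo,trim_hi The trimming window; the predicted CDF is
#'   conditioned on it, matching the comparison the fit optimised. `NULL`
#'   for the unconditioned model CDF.
#' @return A data frame with columns `x`, `empirical`, `predicted`.
#' @export
cdf_overlay_table <- function(fit, trials, condition = c("word", "nonword"),
                              grid = NULL, trim_lo = 0.25, trim_hi = 3.5) {
  condition <- match.arg(condition)
  if (!isTRUE(fit$converged)) stop("fit did not converge")
  s <- signed_sample(trials, condition)
  if (is.null(grid)) grid <- s$values
  grid <- sort(grid)
  emp <- vapply(grid, function(g) mean(s$values <= g), numeric(1))
  if (!is.null(trim_lo) && !is.null(trim_hi)) {
    gb <- predicted_signed_cdf(fit$estimate, condition,
                               c(-trim_hi, -trim_lo, trim_lo, trim_hi))
    g <- predicted_signed_cdf(fit$estimate, condition, grid)
    mass <- (gb[4] - gb[3]) + (gb[2] - gb[1])
    neg <- grid < 0
    pred <- numeric(length(grid))
    pred[neg] <- (g[neg] - gb[1]) / mass
    pred[!neg] <- (g[!neg] - gb[3] + (gb[2] - gb[1])) / mass
    pred <- pmin(pmax(pred, 0), 1)
  } else {
    pred <- predicted_signed_cdf(fit$estimate, condition, grid)
  }
  data.frame(x = grid, empirical = emp, predicted = pred)
}
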