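#' Fitting configuration
#'
#' Controls the per-participant diffusion-model fit. Drift rate and relative
#' starting point are condition-specific; boundary separation, nondecision
#' time and the across-trial variabilities are shared between the word and
#' nonword conditions. Setting `share_zr = TRUE` merges the starting points
#' into one parameter (the more constrained control model); setting
#' `fix_variabilities_at_zero = TRUE` drops `s_v`, `s_zr`, `s_t0` from the
#' search (useful for fast recovery checks on variability-free data).
#'
#' @param share_zr Single relative starting point for both conditions.
#' @param fix_variabilities_at_zero Fix `s_v = s_zr = s_t0 = 0`.
#' @param n_restarts SIMPLEX restarts from jittered starting values (>= 1).
#' @param max_iterations Iteration cap per restart for the Nelder-Mead
#'   search.
#' @param convergence_tolerance Relative convergence tolerance of the
#'   search.
#' @param gh_nodes,gl_nodes,grid_n Quadrature node counts (drift /
#'   starting-point and nondecision) and decision-time grid size used when
#'   evaluating the predicted signed CDF inside the objective.
#' @param trim_lo,trim_hi The RT window the data were trimmed to; the
#'   objective compares the empirical CDF of the trimmed sample with the
#'   model CDF *conditioned on that window*, so that trimming does not bias
#'   the estimates. Set to `NULL` to compare against the unconditioned
#'   model CDF.
#' @return An object of class `fit_config`.
#' @export
fit_config <- function(share_zr = FALSE, fix_variabilities_at_zero = FALSE,
                       n_restarts = 5, max_iterations = 400,
                       convergence_tolerance = 1e-6,
                       gh_nodes = 10, gl_nodes = 6, grid_n = 280,
                       trim_lo = 0.25, trim_hi = 3.5) {
  stopifnot(n_restarts >= 1, max_iterations >= 1)
  structure(list(share_zr = share_zr,
                 fix_variabilities_at_zero = fix_variabilities_at_zero,
                 n_restarts = as.integer(n_restarts),
                 max_iterations = as.integer(max_iterations),
                 convergence_tolerance = convergence_tolerance,
                 gh_nodes = gh_nodes, gl_nodes = gl_nodes, grid_n = grid_n,
                 trim_lo = trim_lo, trim_hi = trim_hi),
            class = "fit_config")
}

#' Signed RT sample
#'
#' Joint representation of choices and response times of one condition on a
#' single axis: word-boundary (upper) responses keep their RT, nonword
#' (lower) responses are negated. The empirical CDF of the signed sample is
#' what the predicted signed CDF ([predicted_signed_cdf()]) is fitted to.
#'
#' @param trials Trial records (trimmed, non-reference rows with responses).
#' @param condition `"word"` or `"nonword"`.
#' @return An object of class `signed_rt_sample`: list with sorted `values`
#'   and count `n`.
#' @export
signed_sample <- function(trials, condition = c("word", "nonword")) {
  condition <- match.arg(condition)
  tr <- trials[!trials$is_reference & trials$condition == condition &
                 !is.na(trials$response) & !is.na(trials$rt), , drop = FALSE]
  if (nrow(tr) == 0) stop("no usable trials for condition '", condition, "'")
  x <- ifelse(tr$response == "word", tr$rt, -tr$rt)
  structure(list(values = sort(x), n = length(x)), class = "signed_rt_sample")
}

#' Kolmogorov-Smirnov distance and p-value
#'
#' `ks_distance` computes the sup distance between the empirical CDF of a
#' signed sample and a predicted CDF, evaluating the predicted CDF at the
#' sample points and taking the larger of the left and right ECDF gaps.
#' `ks_pvalue` converts a distance into the Kolmogorov tail probability
#' using the finite-sample scaling
#' `lambda = D * (sqrt(n) + 0.12 + 0.11 / sqrt(n))` and
#' `Q(lambda) = 2 * sum_k (-1)^(k-1) exp(-2 k^2 lambda^2)`.
#'
#' @param sample A [signed_sample()] (or any object with sorted `values`).
#' @param G The predicted signed CDF: a function, or a numeric vector of
#'   CDF values at `sample$values`.
#' @param D A KS distance in `[0, 1]`.
#' @param n Sample size.
#' @return `ks_distance`: the sup distance; `ks_pvalue`: a p-value in
#'   `[0, 1]`.
#' @examples
#' ks_pvalue(0, 100)        # 1: perfect fit
#' ks_pvalue(0.5, 10)       # ~0.008
#' @export
ks_distance <- function(sample, G) {
  x <- sample$values
  n <- length(x)
  g <- if (is.function(G)) G(x) else G
  if (length(g) != n) stop("G must give one CDF value per sample point")
  i <- seq_len(n)
  max(pmax(abs(i / n - g), abs((i - 1) / n - g)))
}

#' @rdname ks_distance
#' @export
ks_pvalue <- function(D, n) {
  stopifnot(n >= 1, D >= 0, D <= 1)
  lam <- D * (sqrt(n) + 0.12 + 0.11 / sqrt(n))
  min(max(kolmogorov_q(lam), 0), 1)
}

## Kolmogorov tail probability Q(lambda), dual-series evaluation
kolmogorov_q <- function(lam) {
  if (lam < 1e-6) return(1)
  if (lam < 1.18) {
    # small-lambda representation: 1 - sqrt(2 pi)/lam * sum over odd k
    k <- c(1, 3, 5, 7, 9)
    1 - sqrt(2 * pi) / lam * sum(exp(-k^2 * pi^2 / (8 * lam^2)))
  } else {
    k <- 1:25
    2 * sum((-1)^(k - 1) * exp(-2 * k^2 * lam^2))
  }
}

## log p-value, stable when the fit is terrible (p underflows)
ks_log_pvalue <- function(D, n) {
  lam <- D * (sqrt(n) + 0.12 + 0.11 / sqrt(n))
  if (lam > 2.5) return(log(2) - 2 * lam^2)   # leading term dominates
  q <- kolmogorov_q(lam)
  log(max(q, 1e-300))
}

#' Moment-based starting values
#'
#' EZ-style closed-form starting values for the SIMPLEX search: drift and
#' boundary separation from each condition's accuracy and correct-RT mean
#' and variance (accuracy edge-corrected into `[1/(2n), 1 - 1/(2n)]`),
#' nondecision time at 90% of the smallest RT, starting points from the
#' response-proportion asymmetry of each condition, and small fixed
#' variability defaults.
#'
#' @param trials Trimmed trial records containing both conditions, at least
#'   20 trials each.
#' @param fix_variabilities_at_zero Zero the variability starts.
#' @return A [diffusion_params()] object (deterministic in the input).
#' @export
initial_values <- function(trials, fix_variabilities_at_zero = FALSE) {
  tr <- trials[!trials$is_reference & !is.na(trials$response) &
                 !is.na(trials$rt), , drop = FALSE]
  est <- list()
  for (cond in c("word", "nonword")) {
    tc <- tr[tr$condition == cond, , drop = FALSE]
    n <- nrow(tc)
    if (n < 20) stop("need at least 20 trials per condition, got ", n,
                     " for '", cond, "'")
    pc <- mean(tc$correct)
    pc <- min(max(pc, 1 / (2 * n)), 1 - 1 / (2 * n))
    if (abs(pc - 0.5) < 1e-4) pc <- 0.5 + 1e-4
    mrt <- mean(tc$rt[tc$correct])
    vrt <- stats::var(tc$rt[tc$correct])
    ez <- ez_moments(pc, vrt)
    est[[cond]] <- list(v = ez$v, a = ez$a, n = n,
                        f_upper = mean(tc$response == "word"),
                        mrt = mrt)
  }
  a0 <- min(max(mean(c(est$word$a, est$nonword$a)), 0.3), 8)
  v_word0 <- clip(est$word$v, 0.05, 8)
  v_nonword0 <- clip(-est$nonword$v, -8, -0.05)
  zr_word0 <- clip(0.5 + 0.5 * (est$word$f_upper - 0.5), 0.2, 0.8)
  zr_nonword0 <- clip(0.5 + 0.5 * (est$nonword$f_upper - 0.5), 0.2, 0.8)
  t00 <- max(0.9 * min(tr$rt), 0.06)
  if (fix_variabilities_at_zero) {
    sv0 <- szr0 <- st00 <- 0
  } else {
    sv0 <- 0.3
    szr0 <- min(0.1, 1.8 * min(zr_word0, zr_nonword0, 1 - zr_word0,
                               1 - zr_nonword0))
    st00 <- min(0.15, 1.8 * t00)
  }
  diffusion_params(v_word = v_word0, v_nonword = v_nonword0, a = a0,
                   zr_word = zr_word0, zr_nonword = zr_nonword0, t0 = t00,
                   s_v = sv0, s_zr = szr0, s_t0 = st00)
}

clip <- function(x, lo, hi) min(max(x, lo), hi)

## EZ-diffusion moments (s = 1): drift magnitude and boundary from accuracy
## and correct-RT variance
ez_moments <- function(pc, vrt) {
  if (!is.finite(vrt) || vrt <= 0) return(list(v = 1, a = 1.5))
  L <- stats::qlogis(pc)
  x <- L * (L * pc^2 - L * pc + pc - 0.5) / vrt
  if (x <= 0) return(list(v = 1, a = 1.5))
  v <- x^(1 / 4)
  a <- L / v
  if (!is.finite(a) || a <= 0) a <- 1.5
  list(v = v, a = a)
}

## ---- the SIMPLEX fit ------------------------------------------------------

param_vector_names <- function(config) {
  nm <- c("v_word", "v_nonword", "a",
          if (config$share_zr) "zr" else c("zr_word", "zr_nonword"),
          "t0")
  if (!config$fix_variabilities_at_zero) nm <- c(nm, "s_v", "s_zr", "s_t0")
  nm
}

encode_params <- function(p, config) {
  nm <- param_vector_names(config)
  full <- unlist(p[c("v_word", "v_nonword", "a", "zr_word", "zr_nonword",
                     "t0", "s_v", "s_zr", "s_t0")])
  if (config$share_zr) full["zr"] <- mean(full[c("zr_word", "zr_nonword")])
  unname(full[nm])
}

decode_params <- function(theta, config) {
  nm <- param_vector_names(config)
  v <- stats::setNames(theta, nm)
  zr_w <- if (config$share_zr) v[["zr"]] else v[["zr_word"]]
  zr_n <- if (config$share_zr) v[["zr"]] else v[["zr_nonword"]]
  sv <- if (config$fix_variabilities_at_zero) 0 else v[["s_v"]]
  szr <- if (config$fix_variabilities_at_zero) 0 else v[["s_zr"]]
  st0 <- if (config$fix_variabilities_at_zero) 0 else v[["s_t0"]]
  list(v_word = v[["v_word"]], v_nonword = v[["v_nonword"]], a = v[["a"]],
       zr_word = zr_w, zr_nonword = zr_n, t0 = v[["t0"]],
       s_v = sv, s_zr = szr, s_t0 = st0, s = 1)
}

## KS statistics of both conditions at a parameter set.  When a trimming
## window is configured, the model CDF is conditioned on the window (the
## sample only contains RTs inside it) before the comparison.
signed_ks_eval <- function(p, samples, config) {
  lo <- config$trim_lo
  hi <- config$trim_hi
  windowed <- !is.null(lo) && !is.null(hi)
  out <- list()
  for (cond in names(samples)) {
    s <- samples[[cond]]
    nodes <- signed_cdf_nodes(p, cond, config$gh_nodes, config$gl_nodes)
    t0_min <- p$t0 - p$s_t0 / 2
    xmax <- max(abs(s$values), if (windowed) hi else NULL)
    tau_grid <- seq(0, max(xmax - t0_min, 0.5), length.out = config$grid_n)
    mix <- wfpt_mix_cdf_grid_cpp(tau_grid, p$a, nodes$v, nodes$vw,
                                 nodes$zr, nodes$zrw)
    x <- if (windowed) c(s$values, -hi, -lo, lo, hi) else s$values
    g <- signed_cdf_from_grid(x, tau_grid, mix, nodes$t0, nodes$t0w)
    if (windowed) {
      n <- s$n
      gb <- g[n + 1:4]                      # G(-hi), G(-lo), G(lo), G(hi)
      g <- g[seq_len(n)]
      mass <- (gb[4] - gb[3]) + (gb[2] - gb[1])
      if (mass < 1e-8) {
        g <- rep(0, n)                      # degenerate: model misses window
      } else {
        neg <- s$values < 0
        g[neg] <- (g[neg] - gb[1]) / mass
        g[!neg] <- (g[!neg] - gb[3] + (gb[2] - gb[1])) / mass
      }
    }
    D <- ks_distance(s, g)
    out[[cond]] <- list(D = D, logp = ks_log_pvalue(D, s$n),
                        p = ks_pvalue(D, s$n))
  }
  out
}

#' Fit the diffusion model to one participant
#'
#' Estimates the condition-constrained diffusion model from a participant's
#' trimmed trials by maximising the sum of the log KS p-values of the word
#' and nonword signed RT distributions with a Nelder-Mead (SIMPLEX) search.
#' Infeasible parameter proposals receive a penalty objective; the best of
#' `n_restarts` jittered starts is returned. Free parameters are the two
#' drifts, boundary separation, the starting point(s), nondecision time and
#' (unless fixed) the three across-trial variabilities.
#'
#' @param trials Trimmed trial records of one participant with both
#'   conditions present.
#' @param config A [fit_config()].
#' @param seed Optional seed for the restart jitter.
#' @return An object of class `fit_result`: the `estimate`
#'   ([diffusion_params()]), per-condition KS statistics `ks_D_*` and
#'   p-values `ks_p_*`, the `objective` (sum of log p-values), trial counts,
#'   `converged`, and `restarts_used`. On total failure `converged` is
#'   `FALSE` (no exception).
#' @export
fit_participant <- function(trials, config = fit_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  samples <- list(word = signed_sample(trials, "word"),
                  nonword = signed_sample(trials, "nonword"))
  min_rt <- min(abs(c(samples$word$values, samples$nonword$values)))

  # Objective: sum of log KS p-values, with a small KS-distance term that
  # breaks ties on the p ~ 1 plateau where the p-value alone is flat.
  objective <- function(theta) {
    p <- decode_params(theta, config)
    if (!params_feasible(p, min_rt)) return(1e10)
    ks <- signed_ks_eval(p, samples, config)
    tie <- 0.01 * (ks$word$D * sqrt(samples$word$n) +
                     ks$nonword$D * sqrt(samples$nonword$n))
    -(ks$word$logp + ks$nonword$logp) + tie
  }

  start0 <- tryCatch(
    encode_params(initial_values(trials, config$fix_variabilities_at_zero),
                  config),
    error = function(e) NULL)
  if (is.null(start0))
    return(failed_fit(samples, config))

  run_nm <- function(theta, maxit, reltol) {
    tryCatch(
      stats::optim(theta, objective, method = "Nelder-Mead",
                   control = list(maxit = maxit, reltol = reltol)),
      error = function(e) NULL)
  }

  best <- NULL
  converged <- FALSE
  for (r in seq_len(config$n_restarts)) {
    theta0 <- if (r == 1) start0 else restart_values(start0, r, config)
    # two chained runs: restarting Nelder-Mead rebuilds the simplex, which
    # recovers progress lost to simplex collapse in the flat directions
    opt <- run_nm(theta0, config$max_iterations, config$convergence_tolerance)
    if (is.null(opt) || opt$value >= 1e9) next
    opt2 <- run_nm(opt$par, config$max_iterations, config$convergence_tolerance)
    if (!is.null(opt2) && opt2$value < opt$value) opt <- opt2
    if (is.null(best) || opt$value < best$value) best <- opt
    if (opt$convergence == 0) converged <- TRUE
  }
  if (is.null(best)) return(failed_fit(samples, config))
  # polish the winner; a plateaued polish step counts as converged
  for (i in 1:2) {
    prev <- best$value
    opt <- run_nm(best$par, 800, config$convergence_tolerance / 10)
    if (!is.null(opt)) {
      if (opt$value < best$value) best <- opt
      # the polish phase plateauing (objective change below 0.01 on the
      # log-p scale, i.e. p-values stable to ~1%) counts as converged
      if (opt$convergence == 0 || prev - opt$value < 1e-2) converged <- TRUE
    }
  }

  est <- decode_params(best$par, config)
  class(est) <- "diffusion_params"
  ks <- signed_ks_eval(est, samples, config)
  structure(list(estimate = est,
                 ks_D_word = ks$word$D, ks_D_nonword = ks$nonword$D,
                 ks_p_word = ks$word$p, ks_p_nonword = ks$nonword$p,
                 objective = ks$word$logp + ks$nonword$logp,
                 n_word = samples$word$n, n_nonword = samples$nonword$n,
                 converged = converged,
                 restarts_used = config$n_restarts),
            class = "fit_result")
}

## Restart starting values: the main parameters get multiplicative +-15%
## jitter; the across-trial variabilities (whose directions of the KS
## objective are nearly flat, so jitter around one value never explores
## them) cycle through a coarse lattice of low/high combinations.
restart_values <- function(theta, r, config, tries = 20) {
  nm <- param_vector_names(config)
  n_main <- length(nm) - if (config$fix_variabilities_at_zero) 0 else 3
  lattice <- list(c(0.3, 0.35), c(0.3, 1.4), c(0.9, 0.35), c(0.9, 1.4))
  for (i in seq_len(tries)) {
    th <- theta
    th[seq_len(n_main)] <- theta[seq_len(n_main)] *
      (1 + stats::runif(n_main, -0.15, 0.15))
    if (!config$fix_variabilities_at_zero) {
      lat <- lattice[[(r - 2) %% length(lattice) + 1]]
      zr_idx <- if (config$share_zr) which(nm == "zr") else
        which(nm %in% c("zr_word", "zr_nonword"))
      zmin <- min(th[zr_idx], 1 - th[zr_idx])
      t0_idx <- which(nm == "t0")
      th[nm == "s_v"] <- lat[1]
      th[nm == "s_zr"] <- lat[2] * zmin
      th[nm == "s_t0"] <- min(0.2, 1.6 * th[t0_idx])
    }
    p <- decode_params(th, config)
    if (params_feasible(p)) return(th)
  }
  theta
}

failed_fit <- function(samples, config) {
  structure(list(estimate = NULL,
                 ks_D_word = NA_real_, ks_D_nonword = NA_real_,
                 ks_p_word = NA_real_, ks_p_nonword = NA_real_,
                 objective = NA_real_,
                 n_word = if (!is.null(samples$word)) samples$word$n else 0L,
                 n_nonword = if (!is.null(samples$nonword)) samples$nonword$n else 0L,
                 converged = FALSE,
                 restarts_used = config$n_restarts),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("Diffusion model fit (KS objective):\n")
  if (!is.null(x$estimate)) {
    print(x$estimate)
    cat(sprintf("KS D (word %.4f, nonword %.4f), p (%.4f, %.4f)\n",
                x$ks_D_word, x$ks_D_nonword, x$ks_p_word, x$ks_p_nonword))
  }
  cat("converged:", x$converged, " objective:", round(x$objective, 3), "\n")
  invisible(x)
}

#' Fit a whole cohort
#'
#' Runs [fit_participant()] for every participant in a trial table and
#' collects the estimates into one data frame (one row per participant:
#' parameter estimates, per-condition KS D and p, objective, convergence,
#' trial counts).
#'
#' @param trials Trimmed trial records for several participants.
#' @param config A [fit_config()].
#' @param seed Optional seed; participant fits use sequential sub-seeds.
#' @param verbose Print one line per participant.
#' @return A data frame of per-participant fits.
#' @export
fit_cohort <- function(trials, config = fit_config(), seed = NULL,
                       verbose = FALSE) {
  ids <- unique(trials$participant_id)
  rows <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    tr <- trials[trials$participant_id == ids[i], , drop = FALSE]
    sub_seed <- if (is.null(seed)) NULL else seed + i
    fit <- fit_participant(tr, config, seed = sub_seed)
    rows[[i]] <- fit_to_row(ids[i], fit)
    if (verbose)
      cat(sprintf("fit %s: objective %.2f converged %s\n", ids[i],
                  fit$objective, fit$converged))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

fit_to_row <- function(id, fit) {
  est <- fit$estimate
  if (is.null(est))
    est <- list(v_word = NA, v_nonword = NA, a = NA, zr_word = NA,
                zr_nonword = NA, t0 = NA, s_v = NA, s_zr = NA, s_t0 = NA)
  data.frame(participant_id = id,
             v_word = est$v_word, v_nonword = est$v_nonword, a = est$a,
             zr_word = est$zr_word, zr_nonword = est$zr_nonword,
             t0 = est$t0, s_v = est$s_v, s_zr = est$s_zr, s_t0 = est$s_t0,
             ks_D_word = fit$ks_D_word, ks_D_nonword = fit$ks_D_nonword,
             ks_p_word = fit$ks_p_word, ks_p_nonword = fit$ks_p_nonword,
             objective = fit$objective, converged = fit$converged,
             restarts_used = fit$restarts_used,
             n_word = fit$n_word, n_nonword = fit$n_nonword,
             stringsAsFactors = FALSE)
}

#' @rdname table_io
#' @param fits A per-participant fit table from [fit_cohort()].
#' @export
write_fits <- function(fits, path) {
  utils::write.csv(fits, path, row.names = FALSE, quote = FALSE)
  invisible(fits)
}

#' @rdname table_io
#' @export
read_fits <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$converged <- as.logical(df$converged)
  df
}
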