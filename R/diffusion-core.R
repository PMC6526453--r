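#' Diffusion model parameter set
#'
#' Bundles the parameters of the Ratcliff diffusion model for a two-condition
#' (word/nonword) lexical decision task: condition-specific drift rates and
#' relative starting points, a common boundary separation, nondecision time,
#' and across-trial variabilities. The within-trial diffusion coefficient is
#' fixed at `s = 1`, the scaling convention under which all other parameters
#' are expressed.
#'
#' @param v_word Drift rate in the word condition (evidence/s); positive
#'   values drive the process toward the upper ("word") boundary.
#' @param v_nonword Drift rate in the nonword condition; expected negative.
#' @param a Boundary separation (> 0).
#' @param zr_word,zr_nonword Relative starting points in (0, 1).
#' @param t0 Nondecision time in seconds (encoding + motor).
#' @param s_v Across-trial drift standard deviation (normal), >= 0.
#' @param s_zr Across-trial range of the relative starting point (uniform
#'   full width); `zr_c +- s_zr/2` must stay inside (0, 1) for both
#'   conditions.
#' @param s_t0 Across-trial range of the nondecision time (uniform full
#'   width, seconds); `t0 - s_t0/2` must be >= 0.
#'
#' @return An object of class `diffusion_params` (a named list).
#' @examples
#' diffusion_params(v_word = 1.5, v_nonword = -1.9, a = 2.1,
#'                  zr_word = 0.72, zr_nonword = 0.36, t0 = 0.35,
#'                  s_v = 0.66, s_zr = 0.26, s_t0 = 0.18)
#' @export
diffusion_params <- function(v_word, v_nonword, a, zr_word, zr_nonword, t0,
                             s_v = 0, s_zr = 0, s_t0 = 0) {
  p <- list(v_word = v_word, v_nonword = v_nonword, a = a,
            zr_word = zr_word, zr_nonword = zr_nonword, t0 = t0,
            s_v = s_v, s_zr = s_zr, s_t0 = s_t0, s = 1)
  class(p) <- "diffusion_params"
  validate_diffusion_params(p)
  p
}

#' @export
print.diffusion_params <- function(x, ...) {
  cat("Diffusion model parameters (s = 1):\n")
  v <- unlist(x[setdiff(names(x), "s")])
  print(round(v, 4))
  invisible(x)
}

validate_diffusion_params <- function(p) {
  stopifnot(is.list(p))
  num1 <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)
  for (f in c("v_word", "v_nonword", "a", "zr_word", "zr_nonword",
              "t0", "s_v", "s_zr", "s_t0"))
    if (!num1(p[[f]])) stop("parameter '", f, "' must be a finite number")
  if (p$a <= 0) stop("boundary separation 'a' must be positive")
  if (p$s_v < 0 || p$s_zr < 0 || p$s_t0 < 0)
    stop("variability parameters must be non-negative")
  for (c in c("word", "nonword")) {
    zr <- p[[paste0("zr_", c)]]
    if (zr - p$s_zr / 2 <= 0 || zr + p$s_zr / 2 >= 1)
      stop("zr_", c, " +- s_zr/2 must lie strictly inside (0, 1)")
  }
  if (p$t0 - p$s_t0 / 2 < 0) stop("t0 - s_t0/2 must be >= 0")
  if (!is.null(p$s) && p$s != 1) stop("the diffusion coefficient s is fixed at 1")
  invisible(p)
}

## TRUE if p could be a valid parameter set (used as an optimizer penalty test)
params_feasible <- function(p, min_rt = Inf) {
  ok <- tryCatch({ validate_diffusion_params(p); TRUE }, error = function(e) FALSE)
  ok &&
    p$a > 0.1 && p$a < 10 &&
    abs(p$v_word) < 10 && abs(p$v_nonword) < 10 &&
    p$zr_word > 0.02 && p$zr_word < 0.98 &&
    p$zr_nonword > 0.02 && p$zr_nonword < 0.98 &&
    p$t0 > 0.05 && (p$t0 - p$s_t0 / 2) < min_rt &&
    p$s_v < 10 && p$s_zr < 1 && p$s_t0 < 2 * p$t0
}

cond_v <- function(params, condition) {
  switch(condition, word = params$v_word, nonword = params$v_nonword,
         stop("condition must be 'word' or 'nonword'"))
}

cond_zr <- function(params, condition) {
  switch(condition, word = params$zr_word, nonword = params$zr_nonword,
         stop("condition must be 'word' or 'nonword'"))
}

#' Choice probability of the upper boundary
#'
#' Probability that a Wiener diffusion process with drift `v`, boundary
#' separation `a` and relative starting point `zr` (diffusion coefficient
#' s = 1) is absorbed at the upper boundary.
#'
#' @param v Drift rate (may be a vector).
#' @param a Boundary separation (> 0).
#' @param zr Relative starting point in (0, 1).
#' @return Probability of an upper-boundary response, in `[0, 1]`.
#' @examples
#' choice_probability(0, 2, 0.3)   # zero drift: equals zr
#' @export
choice_probability <- function(v, a, zr) {
  n <- max(length(v), length(a), length(zr))
  v <- rep_len(v, n); a <- rep_len(a, n); zr <- rep_len(zr, n)
  if (any(a <= 0)) stop("boundary separation 'a' must be positive")
  if (any(zr <= 0 | zr >= 1)) stop("'zr' must lie strictly inside (0, 1)")
  1 - wfpt_p_lower_cpp(v, a, zr)
}

#' First-passage-time density and distribution
#'
#' Defective density (`fpt_density`) and defective cumulative distribution
#' (`fpt_cdf`) of the decision time at one boundary of a Wiener diffusion
#' process with s = 1 and no across-trial variability. "Defective" means the
#' CDF's limit for large `t` is that boundary's choice probability rather
#' than 1.
#'
#' The density uses two series representations, switching from the
#' small-time (image) series to the large-time (Fourier) series at
#' `t / a^2 = 0.12`; both are adaptively truncated. The CDF integrates the
#' large-time series term by term.
#'
#' @param t Decision time(s) in seconds, > 0 (nondecision time is not
#'   included here).
#' @param v Drift rate.
#' @param a Boundary separation (> 0).
#' @param zr Relative starting point in (0, 1).
#' @param boundary `"upper"` or `"lower"`.
#' @return Density values (1/s) or cumulative probabilities at `t`.
#' @examples
#' fpt_cdf(10, 1, 1, 0.5, "upper")       # close to choice_probability(1,1,0.5)
#' fpt_density(0.3, 2, 1, 0.5, "upper")
#' @export
fpt_density <- function(t, v, a, zr, boundary = c("upper", "lower")) {
  boundary <- match.arg(boundary)
  check_fpt_args(t, v, a, zr)
  wfpt_pdf_cpp(t, v, a, zr, boundary == "upper")
}

#' @rdname fpt_density
#' @export
fpt_cdf <- function(t, v, a, zr, boundary = c("upper", "lower")) {
  boundary <- match.arg(boundary)
  check_fpt_args(t, v, a, zr)
  wfpt_cdf_cpp(t, v, a, zr, boundary == "upper")
}

check_fpt_args <- function(t, v, a, zr) {
  if (any(t <= 0)) stop("decision time 't' must be positive")
  if (length(a) != 1 || a <= 0) stop("boundary separation 'a' must be a positive scalar")
  if (length(zr) != 1 || zr <= 0 || zr >= 1) stop("'zr' must be a scalar in (0, 1)")
  if (length(v) != 1 || !is.finite(v)) stop("'v' must be a finite scalar")
  invisible(TRUE)
}

## ---- quadrature node caches ----------------------------------------------

.quad_cache <- new.env(parent = emptyenv())

## Gauss-Hermite nodes/weights for E[f(Z)], Z ~ N(0,1)
gh_rule <- function(n) {
  key <- paste0("gh", n)
  if (is.null(.quad_cache[[key]])) {
    r <- gauss_hermite_raw(n)
    .quad_cache[[key]] <- list(x = sqrt(2) * r$x, w = r$w / sqrt(pi))
  }
  .quad_cache[[key]]
}

## Gauss-Legendre nodes/weights for E[f(U)], U ~ Uniform(-1/2, 1/2)
gl_rule <- function(n) {
  key <- paste0("gl", n)
  if (is.null(.quad_cache[[key]])) {
    r <- gauss_legendre_raw(n)
    .quad_cache[[key]] <- list(x = r$x / 2, w = r$w / 2)
  }
  .quad_cache[[key]]
}

## Golub-Welsch: nodes/weights from the Jacobi matrix of the orthogonal
## polynomial recurrence (base eigen; no external dependency).
gauss_hermite_raw <- function(n) {
  if (n == 1) return(list(x = 0, w = sqrt(pi)))
  b <- sqrt(seq_len(n - 1) / 2)
  J <- diag(0, n)
  J[cbind(1:(n - 1), 2:n)] <- b
  J[cbind(2:n, 1:(n - 1))] <- b
  e <- eigen(J, symmetric = TRUE)
  list(x = e$values, w = sqrt(pi) * e$vectors[1, ]^2)
}

gauss_legendre_raw <- function(n) {
  if (n == 1) return(list(x = 0, w = 2))
  k <- seq_len(n - 1)
  b <- k / sqrt(4 * k^2 - 1)
  J <- diag(0, n)
  J[cbind(1:(n - 1), 2:n)] <- b
  J[cbind(2:n, 1:(n - 1))] <- b
  e <- eigen(J, symmetric = TRUE)
  list(x = e$values, w = 2 * e$vectors[1, ]^2)
}

## ---- predicted signed CDF -------------------------------------------------

#' Predicted CDF of signed response times
#'
#' The joint distribution of responses and RTs in one condition is
#' represented on a single axis by negating lower-boundary ("nonword"
#' response) RTs: the signed CDF G runs from 0 (fast lower-boundary
#' responses) through the lower-boundary choice probability at 0 to 1 (slow
#' upper-boundary responses). Across-trial variabilities are integrated out
#' by deterministic Gaussian quadrature: Gauss-Hermite for the normal drift
#' distribution, Gauss-Legendre for the uniform starting-point and
#' nondecision-time distributions.
#'
#' With all variabilities zero the construction from [fpt_cdf()] and
#' [choice_probability()] is evaluated exactly at the requested points.
#' Otherwise the mixed defective CDFs are computed on a fine decision-time
#' grid and interpolated linearly (the grid is dense enough that the
#' interpolation error is far below the Monte-Carlo resolution of any
#' realistic sample).
#'
#' @param params A [diffusion_params()] object.
#' @param condition `"word"` or `"nonword"`.
#' @param x Signed times (seconds) at which to evaluate; negative values are
#'   lower-boundary RTs. `-Inf`/`Inf` give 0/1.
#' @param gh_nodes Gauss-Hermite node count for drift variability.
#' @param gl_nodes Gauss-Legendre node count for starting-point and
#'   nondecision variability.
#' @param grid_n Size of the internal decision-time grid.
#' @return Cumulative probabilities G(x), nondecreasing in `x`.
#' @examples
#' p <- diffusion_params(1.5, -1.9, 2, 0.7, 0.35, 0.35)
#' predicted_signed_cdf(p, "word", c(-1, -0.5, 0.5, 1, 2))
#' @export
predicted_signed_cdf <- function(params, condition = c("word", "nonword"), x,
                                 gh_nodes = 20, gl_nodes = 10, grid_n = 400) {
  condition <- match.arg(condition)
  validate_diffusion_params(params)
  stopifnot(is.numeric(x))
  out <- numeric(length(x))
  fin <- is.finite(x)
  out[!fin] <- ifelse(x[!fin] > 0, 1, 0)
  if (!any(fin)) return(out)
  xf <- x[fin]
  v <- cond_v(params, condition)
  zr <- cond_zr(params, condition)
  a <- params$a

  if (params$s_v == 0 && params$s_zr == 0 && params$s_t0 == 0) {
    p_lo <- 1 - choice_probability(v, a, zr)
    tau <- abs(xf) - params$t0
    g <- numeric(length(xf))
    neg <- xf < 0
    g[neg] <- p_lo - ifelse(tau[neg] > 0,
                            wfpt_cdf_cpp(pmax(tau[neg], 1e-12), v, a, zr, FALSE), 0)
    g[!neg] <- p_lo + ifelse(tau[!neg] > 0,
                             wfpt_cdf_cpp(pmax(tau[!neg], 1e-12), v, a, zr, TRUE), 0)
    out[fin] <- g
    return(out)
  }

  nodes <- signed_cdf_nodes(params, condition, gh_nodes, gl_nodes)
  t0_lo <- params$t0 - params$s_t0 / 2
  tau_max <- max(max(abs(xf)) - t0_lo, 0.5)
  tau_grid <- seq(0, tau_max, length.out = grid_n)
  mix <- wfpt_mix_cdf_grid_cpp(tau_grid, a, nodes$v, nodes$vw, nodes$zr, nodes$zrw)
  g <- signed_cdf_from_grid(xf, tau_grid, mix, nodes$t0, nodes$t0w)
  out[fin] <- g
  # remove sub-machine-precision wiggles so G is exactly nondecreasing
  ord <- order(x)
  out[ord] <- cummax(out[ord])
  out
}

## quadrature nodes for one condition's variability mixture
signed_cdf_nodes <- function(params, condition, gh_nodes, gl_nodes) {
  v <- cond_v(params, condition)
  zr <- cond_zr(params, condition)
  if (params$s_v > 0) {
    r <- gh_rule(gh_nodes)
    vn <- v + params$s_v * r$x; vw <- r$w
  } else { vn <- v; vw <- 1 }
  if (params$s_zr > 0) {
    r <- gl_rule(gl_nodes)
    zn <- zr + params$s_zr * r$x; zw <- r$w
  } else { zn <- zr; zw <- 1 }
  if (params$s_t0 > 0) {
    r <- gl_rule(gl_nodes)
    tn <- params$t0 + params$s_t0 * r$x; tw <- r$w
  } else { tn <- params$t0; tw <- 1 }
  list(v = vn, vw = vw, zr = zn, zrw = zw, t0 = tn, t0w = tw)
}

## evaluate G at signed points x from grid CDFs, averaging over t0 nodes
signed_cdf_from_grid <- function(x, tau_grid, mix, t0_nodes, t0_w) {
  h <- tau_grid[2] - tau_grid[1]
  signed_cdf_eval_cpp(x, h, length(tau_grid), mix$F_lower, mix$F_upper,
                      mix$p_lower, t0_nodes, t0_w)
}

#' Simulate diffusion trials
#'
#' Draws two-choice trials from the diffusion model by Euler discretisation
#' of the Wiener process, with per-trial draws of drift (normal), relative
#' starting point (uniform) and nondecision time (uniform). Boundary
#' crossing uses the continuity correction of Broadie, Glasserman and Kou
#' (boundaries moved inward by `0.5826 * sqrt(dt)`), which removes the
#' leading discretisation bias of the crossing probabilities.
#'
#' Uses R's global random number generator; call `set.seed()` for
#' reproducibility.
#'
#' @param n Number of trials.
#' @param params A [diffusion_params()] object.
#' @param condition `"word"` or `"nonword"` (selects drift and starting
#'   point).
#' @param dt Euler step in seconds.
#' @param max_steps Step cap per trial; exceeding it is an error.
#' @param boundary_correction Apply the continuity correction (recommended).
#' @return A data frame with columns `response` (`"upper"`/`"lower"`) and
#'   `rt` (seconds, including the nondecision time draw).
#' @examples
#' p <- diffusion_params(2, -2, 1, 0.5, 0.5, 0.3)
#' set.seed(1)
#' head(simulate_trials(5, p, "word"))
#' @export
simulate_trials <- function(n, params, condition = c("word", "nonword"),
                            dt = 2e-4, max_steps = 1e6,
                            boundary_correction = TRUE) {
  condition <- match.arg(condition)
  validate_diffusion_params(params)
  stopifnot(n >= 1, dt > 0)
  sim <- sim_wiener_cpp(n, cond_v(params, condition), params$a,
                        cond_zr(params, condition), params$t0,
                        params$s_v, params$s_zr, params$s_t0,
                        dt, as.integer(max_steps), boundary_correction)
  data.frame(response = ifelse(sim$response == 1L, "upper", "lower"),
             rt = sim$rt, stringsAsFactors = FALSE)
}
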