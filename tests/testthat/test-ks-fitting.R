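test_that("signed samples negate lower-boundary responses and keep n", {
  tr <- data.frame(participant_id = "p1", session = 1, page = 1, slot = 2:3,
                   condition = "word", is_reference = FALSE,
                   is_practice = FALSE,
                   response = c("word", "nonword"), rt = c(0.7, 0.9),
                   correct = c(TRUE, FALSE), stringsAsFactors = FALSE)
  s <- signed_sample(tr, "word")
  expect_equal(s$values, c(-0.9, 0.7))
  expect_equal(s$n, 2)
  # all one response: all one sign
  tr$response <- "nonword"
  expect_true(all(signed_sample(tr, "word")$values < 0))
  expect_error(signed_sample(tr, "nonword"), "no usable trials")
})

test_that("the KS distance matches its definition", {
  # single point against G = 0.5: half a step
  s1 <- structure(list(values = 0.3, n = 1), class = "signed_rt_sample")
  expect_equal(ks_distance(s1, 0.5), 0.5)
  # sample at exact quantiles (i - 1/2)/n of G: D = 1/(2n)
  n <- 40
  svals <- (seq_len(n) - 0.5) / n
  s <- structure(list(values = svals, n = n), class = "signed_rt_sample")
  expect_equal(ks_distance(s, function(x) x), 1 / (2 * n))
  # brute-force sup over a fine grid agrees
  set.seed(16)
  x <- sort(rnorm(50))
  s <- structure(list(values = x, n = 50), class = "signed_rt_sample")
  G <- pnorm
  d_fn <- ks_distance(s, G)
  grid <- seq(-4, 4, length.out = 20001)
  emp <- vapply(grid, function(g) mean(x <= g), numeric(1))
  d_brute <- max(abs(emp - pnorm(grid)))
  expect_lt(abs(d_fn - d_brute), 1e-3)
  expect_gte(d_fn, d_brute - 1e-12)   # sup is attained at sample points
})

test_that("KS p-values follow the Kolmogorov tail series", {
  expect_equal(ks_pvalue(0, 100), 1)
  # series oracle with 100 terms
  lam <- 0.5 * (sqrt(10) + 0.12 + 0.11 / sqrt(10))
  k <- 1:100
  q_oracle <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * lam^2))
  expect_equal(ks_pvalue(0.5, 10), q_oracle, tolerance = 1e-10)
  expect_equal(round(ks_pvalue(0.5, 10), 4), 0.0082)
  # p decreasing in D at fixed n
  ds <- seq(0.01, 0.9, by = 0.01)
  ps <- vapply(ds, ks_pvalue, numeric(1), n = 30)
  expect_true(all(diff(ps) <= 1e-12))
  # the two series representations agree at the switch point
  expect_equal(pendiff:::kolmogorov_q(1.18 - 1e-9),
               pendiff:::kolmogorov_q(1.18 + 1e-9), tolerance = 1e-6)
  # log p-value matches log(p) where p is representable
  expect_equal(pendiff:::ks_log_pvalue(0.2, 100), log(ks_pvalue(0.2, 100)),
               tolerance = 1e-6)
})

test_that("moment-based starting values are sane and deterministic", {
  tr <- sim_trials(simple_params(), 2500, seed = 17)
  tr <- trim_rts(tr)$trials
  iv1 <- initial_values(tr)
  iv2 <- initial_values(tr)
  expect_identical(unclass(iv1), unclass(iv2))   # no randomness
  # within a factor 2 of the generating values for v and a
  p <- simple_params()
  expect_lt(abs(log(iv1$v_word / p$v_word)), log(2))
  expect_lt(abs(log(-iv1$v_nonword / -p$v_nonword)), log(2))
  expect_lt(abs(log(iv1$a / p$a)), log(2))
  expect_lt(iv1$t0, min(tr$rt))
  # symmetric data: drift near zero, start near centre
  sym <- data.frame(participant_id = "p1", session = 1, page = 1,
                    slot = 2, condition = rep(c("word", "nonword"), each = 40),
                    is_reference = FALSE, is_practice = FALSE,
                    response = rep(c("word", "nonword"), 40),
                    rt = rep(c(0.5, 0.6, 0.7, 0.8), 20),
                    stringsAsFactors = FALSE)
  sym$correct <- sym$response == sym$condition
  iv <- initial_values(sym)
  expect_lt(abs(iv$zr_word - 0.5), 0.05)
  expect_lt(abs(iv$v_word), 1.1)   # edge-corrected near-zero drift
  expect_error(initial_values(sym[1:30, ]), "at least 20")
})

test_that("fitting recovers no-variability parameters from simulated data", {
  p <- simple_params()
  tr <- sim_trials(p, 5000, seed = 18)
  tr <- trim_rts(tr)$trials
  fit <- fit_participant(tr, quick_config(), seed = 19)
  expect_true(fit$converged)
  expect_lt(abs(fit$estimate$v_word - p$v_word), 0.1)
  expect_lt(abs(fit$estimate$v_nonword - p$v_nonword), 0.15)
  expect_lt(abs(fit$estimate$a - p$a), 0.12)
  expect_lt(abs(fit$estimate$t0 - p$t0), 0.02)
  expect_lt(abs(fit$estimate$zr_word - p$zr_word), 0.04)
  # fitted p-values are not in the misfit region
  expect_gt(model_p(fit), 0.05)
})

test_that("degenerate one-boundary data do not crash the fitter", {
  tr <- sim_trials(diffusion_params(7, -7, 1, 0.5, 0.5, 0.3), 60, seed = 20)
  tr$response <- "word"          # all responses at one boundary
  tr$correct <- tr$response == tr$condition
  expect_error(fit <- fit_participant(tr, quick_config(), seed = 21), NA)
  expect_s3_class(fit, "fit_result")
})

test_that("relabelling conditions swaps the condition-specific estimates", {
  p <- diffusion_params(1.2, -1.2, 1.6, 0.62, 0.38, 0.3)
  tr <- sim_trials(p, 2000, seed = 22)
  tr <- trim_rts(tr)$trials
  sw <- tr
  sw$condition <- ifelse(tr$condition == "word", "nonword", "word")
  sw$response <- ifelse(tr$response == "word", "nonword", "word")
  sw$rt <- tr$rt
  sw$correct <- sw$response == sw$condition
  f1 <- fit_participant(tr, quick_config(), seed = 23)
  f2 <- fit_participant(sw, quick_config(), seed = 23)
  # swapping labels mirrors drift and starting point across conditions
  expect_lt(abs(f1$estimate$v_word + f2$estimate$v_nonword), 0.25)
  expect_lt(abs(f1$estimate$zr_word - (1 - f2$estimate$zr_nonword)), 0.08)
})
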