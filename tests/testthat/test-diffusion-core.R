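test_that("choice probabilities match closed forms and conserve mass", {
  # zero drift: P_upper equals the relative starting point
  expect_equal(choice_probability(0, 2, 0.3), 0.3, tolerance = 1e-12)
  # unbiased start: P_upper = logistic(2 v z), here plogis(1)
  expect_equal(choice_probability(1, 1, 0.5), plogis(1), tolerance = 1e-10)
  set.seed(11)
  for (i in 1:200) {
    v <- runif(1, -6, 6); a <- runif(1, 0.3, 4); zr <- runif(1, 0.05, 0.95)
    p_up <- choice_probability(v, a, zr)
    p_lo <- 1 - p_up
    # conservation
    expect_lt(abs(p_up + p_lo - 1), 1e-10)
    # reflection symmetry
    expect_lt(abs(p_up - (1 - choice_probability(-v, a, 1 - zr))), 1e-9)
  }
  # extreme drift stays in [0, 1] without overflow
  expect_equal(choice_probability(9.9, 9.9, 0.5), 1, tolerance = 1e-10)
  expect_equal(choice_probability(-9.9, 9.9, 0.5), 0, tolerance = 1e-10)
})

test_that("first-passage density integrates to the choice probabilities", {
  set.seed(12)
  for (i in 1:10) {
    v <- runif(1, -4, 4); a <- runif(1, 0.5, 3); zr <- runif(1, 0.15, 0.85)
    up <- integrate(function(t) fpt_density(t, v, a, zr, "upper"),
                    0, Inf, rel.tol = 1e-9)$value
    lo <- integrate(function(t) fpt_density(t, v, a, zr, "lower"),
                    0, Inf, rel.tol = 1e-9)$value
    expect_lt(abs(up + lo - 1), 1e-5)
    expect_lt(abs(up - choice_probability(v, a, zr)), 1e-5)
  }
})

test_that("density and CDF are mutually consistent", {
  set.seed(13)
  for (i in 1:8) {
    v <- runif(1, -3, 3); a <- runif(1, 0.5, 3); zr <- runif(1, 0.2, 0.8)
    tt <- runif(3, 0.05, 1.5)
    for (t in tt) {
      # CDF equals the integral of the density
      num <- integrate(function(u) fpt_density(u, v, a, zr, "lower"),
                       0, t, rel.tol = 1e-10)$value
      expect_lt(abs(num - fpt_cdf(t, v, a, zr, "lower")), 1e-6)
      # numerical derivative of the CDF equals the density
      h <- 1e-5
      der <- (fpt_cdf(t + h, v, a, zr, "upper") -
                fpt_cdf(t - h, v, a, zr, "upper")) / (2 * h)
      expect_lt(abs(der - fpt_density(t, v, a, zr, "upper")), 1e-4)
    }
    # monotone, defective limits
    grid <- seq(0.01, 20, length.out = 200)
    Fv <- fpt_cdf(grid, v, a, zr, "upper")
    expect_true(all(diff(Fv) >= -1e-12))
    expect_lt(abs(Fv[200] - choice_probability(v, a, zr)), 1e-8)
  }
  # symmetric case: the two boundaries are indistinguishable
  tt <- c(0.05, 0.2, 1)
  expect_equal(fpt_density(tt, 0, 1.4, 0.5, "upper"),
               fpt_density(tt, 0, 1.4, 0.5, "lower"), tolerance = 1e-12)
  # domain errors
  expect_error(fpt_cdf(-1, 1, 1, 0.5), "positive")
  expect_error(fpt_density(0.5, 1, -1, 0.5), "positive")
})

test_that("the signed CDF degenerates exactly to the no-variability form", {
  p <- simple_params()
  x <- c(-2, -0.8, -0.4, 0.4, 0.9, 1.6, 3)
  g <- predicted_signed_cdf(p, "word", x)
  p_lo <- 1 - choice_probability(p$v_word, p$a, p$zr_word)
  expected <- ifelse(x < 0,
                     p_lo - fpt_cdf(pmax(-x - p$t0, 1e-12), p$v_word, p$a,
                                    p$zr_word, "lower"),
                     p_lo + fpt_cdf(pmax(x - p$t0, 1e-12), p$v_word, p$a,
                                    p$zr_word, "upper"))
  expect_equal(g, expected, tolerance = 1e-10)
  # normalisation at the ends
  expect_equal(predicted_signed_cdf(p, "word", c(-Inf, Inf)), c(0, 1))
})

test_that("the signed CDF with variabilities is a proper monotone mixture", {
  p <- diffusion_params(1.5, -1.9, 2, 0.7, 0.35, 0.35,
                        s_v = 0.6, s_zr = 0.2, s_t0 = 0.15)
  x <- sort(c(seq(-3.4, -0.3, length.out = 100),
              seq(0.3, 3.4, length.out = 100)))
  g <- predicted_signed_cdf(p, "word", x)
  expect_true(all(diff(g) >= 0))
  expect_true(all(g >= 0 & g <= 1))
  expect_equal(predicted_signed_cdf(p, "nonword", c(-Inf, Inf)), c(0, 1))
  # quadrature against a much denser reference
  g_dense <- predicted_signed_cdf(p, "word", x, gh_nodes = 40,
                                  gl_nodes = 25, grid_n = 4000)
  expect_lt(max(abs(g - g_dense)), 2e-3)
})

test_that("simulated trials respect drift direction and nondecision floor", {
  p <- diffusion_params(6, -6, 1, 0.5, 0.5, 0.3, s_t0 = 0.1)
  set.seed(14)
  s <- simulate_trials(1000, p, "word")
  expect_gte(mean(s$response == "upper"), 0.99)   # strong drift
  expect_true(all(s$rt >= 0.3 - 0.05))            # t0 - s_t0/2 floor
  s2 <- simulate_trials(1000, p, "nonword")
  expect_gte(mean(s2$response == "lower"), 0.99)
})

test_that("simulator choice fractions match the analytic prediction", {
  p <- group_defaults("younger")$means
  set.seed(15)
  n <- 20000
  s <- simulate_trials(n, p, "word")
  p_up_pred <- 1 - predicted_signed_cdf(p, "word", 0)
  mc_sd <- sqrt(p_up_pred * (1 - p_up_pred) / n)
  expect_lt(abs(mean(s$response == "upper") - p_up_pred), 3 * mc_sd)
})
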