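test_that("the mixed ANOVA reproduces hand-derived F statistics", {
  res <- mixed_anova(anova_fixture())
  expect_equal(res$value[res$effect == "group"], 3.24, tolerance = 1e-10)
  expect_equal(res$value[res$effect == "condition"], 121, tolerance = 1e-10)
  expect_equal(res$value[res$effect == "group:condition"], 25,
               tolerance = 1e-10)
  expect_equal(res$df1, c(1, 1, 1))
  expect_equal(res$df2, c(2, 2, 2))
  expect_true(all(res$eta_squared >= 0 & res$eta_squared <= 1))
})

test_that("the mixed ANOVA matches the aov error decomposition exactly", {
  set.seed(31)
  for (n_per_group in c(2, 3, 4)) {
    d <- random_anova_data(n_per_group)
    mine <- mixed_anova(d)
    ref <- summary(aov(value ~ group * condition + Error(subject / condition),
                       data = d))
    f_between <- ref[["Error: subject"]][[1]]["group", "F value"]
    f_within <- ref[["Error: subject:condition"]][[1]][
      c("condition", "group:condition"), "F value"]
    expect_equal(mine$value, unname(c(f_between, f_within)),
                 tolerance = 1e-10)
  }
})

test_that("constant data give zero F; relabelling conditions keeps F_group", {
  d <- anova_fixture()
  d0 <- d; d0$value <- 5
  res0 <- mixed_anova(d0)
  expect_equal(res0$value, c(0, 0, 0))
  d2 <- d
  d2$condition <- ifelse(d$condition == "c1", "c2", "c1")
  expect_equal(mixed_anova(d2)$value[1], mixed_anova(d)$value[1])
  # missing cells are a data error
  expect_error(mixed_anova(d[-1, ]), "exactly one value")
})

test_that("Bonferroni follow-ups scale and cap the p-values", {
  d <- anova_fixture()
  fu <- pairwise_bonferroni(d)
  expect_equal(nrow(fu), 4)
  expect_true(all(fu$p_adjusted >= fu$p_raw - 1e-15))
  expect_true(all(fu$p_adjusted <= 1))
  expect_equal(fu$p_adjusted, pmin(1, fu$p_raw * 4))
  # family of one: adjusted equals raw
  one <- pairwise_bonferroni(d, list(list(type = "between", condition = "c1")))
  expect_equal(one$p_adjusted, one$p_raw)
  # identical group means: t = 0 and zero effect size
  dz <- d; dz$value <- rep(c(1, 2), 4)
  z <- pairwise_bonferroni(dz, list(list(type = "between", condition = "c1")))
  expect_equal(z$value, 0)
  expect_equal(z$eta_squared, 0)
  expect_error(pairwise_bonferroni(d, list()), "empty")
})

test_that("between-group t-tests use pooled variance and flip sign on swap", {
  r <- ttest_between(c(1, 2, 3, 4, 5, 6), rep(c("A", "B"), each = 3))
  expect_equal(r$value, -3.674, tolerance = 1e-3)
  expect_equal(r$df1, 4)
  r2 <- ttest_between(c(4, 5, 6, 1, 2, 3), rep(c("A", "B"), each = 3))
  expect_equal(r2$value, -r$value)
  # equal means: t = 0
  r0 <- ttest_between(c(1, 2, 1, 2), rep(c("A", "B"), each = 2))
  expect_equal(r0$value, 0)
  expect_error(ttest_between(c(1, 1, 1, 1), rep(c("A", "B"), each = 2)),
               "zero pooled variance")
})

test_that("nonword drift sign conversion is an involution", {
  fits <- data.frame(v_word = c(1.5, 2), v_nonword = c(-1.944, -2.1))
  conv <- drift_sign_convert(fits)
  expect_equal(conv$v_nonword, c(1.944, 2.1))
  expect_equal(conv$v_word, fits$v_word)
  expect_equal(drift_sign_convert(conv), fits)
})

test_that("partial correlations follow the control formula", {
  # formula oracle: r_xy = 0.6, r_xz = r_yz = 0.5 -> 0.35 / 0.75
  expect_equal((0.6 - 0.5 * 0.5) / sqrt((1 - 0.25) * (1 - 0.25)),
               0.4667, tolerance = 1e-4)
  # the function, against the same formula applied to sample correlations
  set.seed(33)
  g <- rep(c("A", "B"), each = 30)
  z <- as.numeric(g == "B")
  v <- 0.8 * z + rnorm(60)
  vocab <- 0.8 * z + 0.5 * v + rnorm(60)
  out <- correlations(v, vocab, g)
  r_xz <- cor(v, z); r_yz <- cor(vocab, z); r_xy <- cor(v, vocab)
  manual <- (r_xy - r_xz * r_yz) / sqrt((1 - r_xz^2) * (1 - r_yz^2))
  expect_equal(out$r_partial, manual, tolerance = 1e-12)
  expect_equal(out$r_bivariate, r_xy, tolerance = 1e-12)
  # no group variance: partial equals bivariate
  out2 <- correlations(v, vocab, rep("A", 60))
  expect_equal(out2$r_partial, out2$r_bivariate)
  expect_error(correlations(rep(1, 10), rnorm(10), rep(c("A", "B"), 5)),
               "zero variance")
})

test_that("participant-level summaries average within groups", {
  tr <- data.frame(participant_id = "p1", session = 1, page = 1, slot = 2:3,
                   condition = "word", is_reference = FALSE,
                   is_practice = FALSE,
                   response = c("word", "nonword"), rt = c(0.6, 1.0),
                   stringsAsFactors = FALSE)
  tr$correct <- tr$response == tr$condition
  tr2 <- rbind(tr, within(tr, { condition <- "nonword"
                                correct <- response == condition }))
  groups <- data.frame(participant_id = "p1", group = "younger")
  s <- table2_summary(tr2, groups)
  w <- s[s$condition == "word", ]
  expect_equal(w$accuracy_mean, 0.5)
  expect_equal(w$rt_correct_ms_mean, 600)
  expect_equal(w$rt_error_ms_mean, 1000)
  expect_true(all(s$accuracy_mean >= 0 & s$accuracy_mean <= 1))
})
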