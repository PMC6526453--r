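test_that("degenerate truth draws return the profile means exactly", {
  prof <- group_profile("younger", param_sds = zero_sds())
  set.seed(24)
  truth <- draw_participant_truth(prof)
  expect_equal(unclass(truth$params)[1:9],
               unclass(group_defaults("younger")$means)[1:9])
})

test_that("vocabulary-drift coupling induces the target correlation", {
  prof <- group_profile("older", vocab_drift_corr = 0.5)
  set.seed(25)
  draws <- replicate(10000, {
    t <- draw_participant_truth(prof)
    c(t$vocabulary, t$params$v_word)
  })
  r <- cor(draws[1, ], draws[2, ])
  expect_lt(abs(r - 0.5), 0.05)
})

test_that("drawn parameters always satisfy the model invariants", {
  prof <- group_profile("younger")   # includes sizeable zr and s_zr spread
  set.seed(26)
  for (i in 1:200) {
    t <- draw_participant_truth(prof)
    p <- t$params
    expect_gt(p$zr_word - p$s_zr / 2, 0)
    expect_lt(p$zr_word + p$s_zr / 2, 1)
    expect_gt(p$zr_nonword - p$s_zr / 2, 0)
    expect_lt(p$zr_nonword + p$s_zr / 2, 1)
    expect_gte(p$t0 - p$s_t0 / 2, 0)
    expect_gt(p$a, 0)
  }
})

test_that("generated cohorts have the right structure and round-trip", {
  profs <- list(group_profile("younger", n_participants = 2,
                              param_sds = zero_sds(),
                              contamination_rate = 0))
  coh <- generate_cohort(profs, tiny_design(), seed = 27)
  expect_equal(nrow(coh$schedule), 4 * 3 * 11)
  expect_equal(nrow(coh$truth), 2)
  expect_equal(nrow(coh$trials), 2 * nrow(coh$schedule))
  # every trial's participant exists in the truth table (foreign key)
  expect_true(all(coh$trials$participant_id %in% coh$truth$participant_id))
  expect_true(all(coh$strokes$participant_id %in% coh$truth$participant_id))
  # stroke-to-trial inversion is the identity on the generated records
  tr2 <- strokes_to_trials(coh$strokes, coh$schedule,
                           tiny_design()$n_practice_sessions)
  expect_identical(tr2, coh$trials)
  # all non-reference trials carry a response and a positive RT
  nr <- coh$trials[!coh$trials$is_reference, ]
  expect_true(all(!is.na(nr$response)))
  expect_true(all(nr$rt > 0))
  # practice sessions flagged
  expect_true(all(coh$trials$is_practice == (coh$trials$session <= 1)))
})

test_that("cohort accuracy and speed reproduce the expected group ordering", {
  # reduced design: enough trials to order group means reliably
  d <- experiment_design(n_sessions = 10, n_practice_sessions = 1)
  profs <- list(group_profile("younger", n_participants = 4,
                              param_sds = zero_sds(), contamination_rate = 0),
                group_profile("older", n_participants = 4,
                              param_sds = zero_sds(), contamination_rate = 0))
  coh <- generate_cohort(profs, d, seed = 28)
  tr <- trim_rts(coh$trials)$trials
  tr <- tr[!tr$is_reference, ]
  tr$group <- sub("_.*", "", tr$participant_id)
  acc <- tapply(tr$correct, list(tr$group, tr$condition), mean)
  rtc <- tapply(tr$rt[tr$correct], list(tr$group[tr$correct],
                                        tr$condition[tr$correct]), mean)
  # older adults: more accurate on words, slower on nonwords
  expect_gt(acc["older", "word"], acc["younger", "word"])
  expect_gt(rtc["older", "nonword"], rtc["younger", "nonword"])
})

test_that("contamination replaces the configured fraction of trials", {
  prof <- group_profile("younger", n_participants = 1,
                        param_sds = zero_sds(), contamination_rate = 0.3)
  # contaminants are uniform on the trimming window: they survive trimming
  coh <- generate_cohort(list(prof), tiny_design(), seed = 29)
  out <- trim_rts(coh$trials)
  expect_lt(out$fraction_eliminated, 0.05)
})
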