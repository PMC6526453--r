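test_that("design arithmetic gives the expected stimulus counts", {
  d <- experiment_design()
  expect_equal(d$n_sessions * d$pages_per_session * d$items_per_page, 2211)
  set.seed(1)
  sched <- build_design(d)
  expect_equal(nrow(sched), 2211)
  expect_equal(sum(sched$is_reference), 201)
  expect_equal(sum(!sched$is_reference), 2010)
  # per-session quotas
  tab <- table(sched$session[!sched$is_reference],
               sched$condition[!sched$is_reference])
  expect_true(all(tab[, "word"] == 15))
  expect_true(all(tab[, "nonword"] == 15))
  # one reference per page, always slot 1
  expect_true(all(sched$slot[sched$is_reference] == 1))
  expect_equal(sum(sched$is_reference), 67 * 3)
})

test_that("small custom designs are laid out consistently", {
  d <- experiment_design(n_sessions = 1, pages_per_session = 1,
                         items_per_page = 3, n_practice_sessions = 0,
                         words_per_session = 1, nonwords_per_session = 1)
  set.seed(2)
  sched <- build_design(d)
  expect_equal(nrow(sched), 3)
  expect_equal(sum(sched$is_reference), 1)
})

test_that("inconsistent design configurations are rejected", {
  expect_error(experiment_design(words_per_session = 10),
               "must equal")
  expect_error(experiment_design(n_practice_sessions = 99), "smaller")
  expect_error(experiment_design(items_per_page = 1), "at least 2")
})

test_that("make_nonword preserves length and consonants, replaces vowels", {
  expect_equal(make_nonword("Krnst"), "Krnst")   # nothing to replace
  set.seed(3)
  for (i in 1:50) {
    pool <- generate_stimulus_pool(1, experiment_design())
    w <- pool$word
    nw <- pool$nonword
    expect_equal(nchar(nw), nchar(w))
    wc <- strsplit(w, "")[[1]]
    nc <- strsplit(nw, "")[[1]]
    vowel <- wc %in% c("a", "e", "i", "o", "u")
    expect_equal(nc[!vowel], wc[!vowel])          # consonants in place
    expect_true(all(nc[vowel] != wc[vowel]))      # every vowel changed
    expect_true(all(nc[vowel] %in% c("a", "e", "i", "o", "u")))
  }
  # 'u' after 'q' is retained, other vowels replaced
  set.seed(4)
  nq <- make_nonword("Quark")
  expect_equal(substr(nq, 1, 2), "Qu")
  expect_true(substr(nq, 3, 3) != "a")
  # umlauts are replaced by plain vowels
  set.seed(5)
  nu <- make_nonword("h\u00e4tte")
  expect_true(substr(nu, 2, 2) %in% c("a", "e", "i", "o", "u"))
})

test_that("stimulus pools have the requested size, lengths and determinism", {
  set.seed(6)
  pool <- generate_stimulus_pool(200, experiment_design())
  expect_equal(nrow(pool), 200)
  expect_true(all(nchar(pool$word) %in% 5:7))
  expect_equal(sum(pool$frequency_class == "low"), round(0.467 * 200))
  set.seed(7); p1 <- generate_stimulus_pool(5, experiment_design())
  set.seed(7); p2 <- generate_stimulus_pool(5, experiment_design())
  expect_identical(p1, p2)
})

test_that("stroke differences become RTs; broken chains give no RT", {
  d <- experiment_design(n_sessions = 1, pages_per_session = 1,
                         items_per_page = 3, n_practice_sessions = 0,
                         words_per_session = 1, nonwords_per_session = 1)
  set.seed(8)
  sched <- build_design(d)
  strokes <- data.frame(participant_id = "p1", session = 1, page = 1,
                        slot = 1:3, checkbox = "yes",
                        pen_down = c(0.5, 1.8, 2.9),
                        pen_up = c(1.0, 2.0, 3.1),
                        stringsAsFactors = FALSE)
  tr <- strokes_to_trials(strokes, sched, n_practice_sessions = 0)
  tr <- tr[order(tr$slot), ]
  expect_true(is.na(tr$rt[1]))                   # reference: no RT
  expect_equal(tr$rt[2], 0.8)
  expect_equal(tr$rt[3], 0.9)

  # missing middle stroke: slot 2 missing, slot 3 must NOT use slot 1's pen_up
  tr2 <- strokes_to_trials(strokes[-2, ], sched, n_practice_sessions = 0)
  tr2 <- tr2[order(tr2$slot), ]
  expect_true(is.na(tr2$response[2]))
  expect_true(is.na(tr2$rt[3]))

  # negative RT names the offending slot
  bad <- strokes
  bad$pen_down[2] <- 0.9
  expect_error(strokes_to_trials(bad, sched, n_practice_sessions = 0),
               "slot 2")
})

test_that("RT trimming keeps the closed window and counts eliminations", {
  tr <- data.frame(participant_id = "p1", session = 1, page = 1, slot = 2:5,
                   condition = "word", is_reference = FALSE,
                   is_practice = FALSE, response = "word",
                   rt = c(0.2, 0.3, 3.6, 1.0), correct = TRUE,
                   stringsAsFactors = FALSE)
  out <- trim_rts(tr)
  expect_equal(out$n_eliminated, 2)
  expect_equal(sort(out$trials$rt), c(0.3, 1.0))
  expect_equal(out$fraction_eliminated, 0.5)
  # boundary values are kept (inclusive window)
  tr$rt <- c(0.25, 3.5, 1, 1)
  expect_equal(trim_rts(tr)$n_eliminated, 0)
  expect_equal(trim_rts(tr)$fraction_eliminated, 0)
  # empty input
  out0 <- trim_rts(tr[0, ])
  expect_equal(out0$n_eliminated, 0)
  expect_equal(nrow(out0$trials), 0)
})

test_that("table files round-trip exactly and reject malformed rows", {
  dir <- withr::local_tempdir()
  d <- tiny_design(2)
  set.seed(9)
  sched <- build_design(d)
  p <- file.path(dir, "schedule.csv")
  write_schedule(sched, p)
  back <- read_schedule(p)
  expect_equal(back, as.data.frame(sched[, names(back)]),
               ignore_attr = TRUE)

  strokes <- data.frame(participant_id = "p1", session = 1, page = 1,
                        slot = 1:2, checkbox = c("yes", "no"),
                        pen_down = c(0.5, 1.23456789012345),
                        pen_up = c(1.0, 1.9), stringsAsFactors = FALSE)
  ps <- file.path(dir, "strokes.csv")
  write_strokes(strokes, ps)
  expect_equal(read_strokes(ps), strokes, ignore_attr = TRUE)

  tr <- sim_trials(simple_params(), 30, seed = 10)
  pt <- file.path(dir, "trials.csv")
  write_trials(tr, pt)
  back <- read_trials(pt)
  expect_equal(back, tr[, names(back)], ignore_attr = TRUE)

  # empty record list: header-only file, empty list back
  write_trials(tr[0, ], pt)
  expect_equal(nrow(read_trials(pt)), 0)

  # malformed rt raises a parse error with the line number
  pt <- file.path(dir, "bad.csv")
  writeLines(c("participant_id,session,page,slot,condition,is_reference,is_practice,response,rt_s",
               "p1,1,1,2,word,0,0,word,abc"), pt)
  expect_error(read_trials(pt), "line 2")
})
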