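## Default population profiles for the two age groups: means and SDs of the
## diffusion parameters (drift and starting point per condition; boundary,
## nondecision time and variabilities shared), plus vocabulary-score norms.
group_defaults <- function(label) {
  switch(label,
    younger = list(
      means = diffusion_params(v_word = 1.472, v_nonword = -1.944, a = 2.106,
                               zr_word = 0.724, zr_nonword = 0.359, t0 = 0.345,
                               s_v = 0.662, s_zr = 0.256, s_t0 = 0.183),
      sds = c(v_word = 0.675, v_nonword = 0.645, a = 0.489,
              zr_word = 0.089, zr_nonword = 0.123, t0 = 0.073,
              s_v = 0.191, s_zr = 0.088, s_t0 = 0.052),
      vocab_mean = 72.06, vocab_sd = 12.23),
    older = list(
      means = diffusion_params(v_word = 2.033, v_nonword = -2.069, a = 2.679,
                               zr_word = 0.771, zr_nonword = 0.305, t0 = 0.399,
                               s_v = 0.758, s_zr = 0.215, s_t0 = 0.172),
      sds = c(v_word = 0.602, v_nonword = 0.545, a = 0.540,
              zr_word = 0.107, zr_nonword = 0.125, t0 = 0.071,
              s_v = 0.153, s_zr = 0.062, s_t0 = 0.062),
      vocab_mean = 85.37, vocab_sd = 13.41),
    stop("label must be 'younger' or 'older'"))
}

#' Age-group population profile
#'
#' Describes the population one synthetic age group is drawn from: the mean
#' and between-person SD of every diffusion parameter, vocabulary-score
#' norms, the target correlation between vocabulary and word drift rate, and
#' a contamination rate. Defaults reproduce typical younger (18-36) and
#' older (64-75) adult groups in a paper-based lexical decision experiment.
#'
#' @param label `"younger"` or `"older"` (selects the default parameter
#'   means, SDs and vocabulary norms).
#' @param n_participants Group size.
#' @param param_means A [diffusion_params()] of population means.
#' @param param_sds Named vector of between-person SDs (same names as the
#'   parameter fields); zero SDs give identical participants.
#' @param vocab_mean,vocab_sd Vocabulary score distribution.
#' @param vocab_drift_corr Target correlation between vocabulary and the
#'   true word drift rate.
#' @param contamination_rate Fraction of trials replaced by contaminants
#'   (uniform RT inside the trimming window, random response).
#' @return An object of class `group_profile`.
#' @examples
#' group_profile("older", n_participants = 5)
#' @export
group_profile <- function(label = c("younger", "older"), n_participants = 20,
                          param_means = NULL, param_sds = NULL,
                          vocab_mean = NULL, vocab_sd = NULL,
                          vocab_drift_corr = 0.5, contamination_rate = 0.02) {
  label <- match.arg(label)
  def <- group_defaults(label)
  if (is.null(param_means)) param_means <- def$means
  if (is.null(param_sds)) param_sds <- def$sds
  if (is.null(vocab_mean)) vocab_mean <- def$vocab_mean
  if (is.null(vocab_sd)) vocab_sd <- def$vocab_sd
  validate_diffusion_params(param_means)
  stopifnot(n_participants >= 1, all(param_sds >= 0),
            abs(vocab_drift_corr) < 1,
            contamination_rate >= 0, contamination_rate < 1)
  structure(list(label = label, n_participants = as.integer(n_participants),
                 param_means = param_means, param_sds = param_sds,
                 vocab_mean = vocab_mean, vocab_sd = vocab_sd,
                 vocab_drift_corr = vocab_drift_corr,
                 contamination_rate = contamination_rate),
            class = "group_profile")
}

#' Draw one participant's true parameters and covariate
#'
#' Draws each diffusion parameter independently from a normal distribution
#' with the profile's mean and SD, redrawing any vector that violates the
#' parameter invariants. The word drift rate is coupled to the vocabulary
#' z-score so that the population correlation between vocabulary and true
#' word drift equals `vocab_drift_corr`.
#'
#' @param profile A [group_profile()].
#' @return A list with `params` ([diffusion_params()]) and `vocabulary`.
#' @export
draw_participant_truth <- function(profile) {
  m <- profile$param_means
  s <- profile$param_sds
  rho <- profile$vocab_drift_corr
  z_vocab <- stats::rnorm(1)
  vocab <- profile$vocab_mean + profile$vocab_sd * z_vocab
  nm <- c("v_word", "v_nonword", "a", "zr_word", "zr_nonword",
          "t0", "s_v", "s_zr", "s_t0")
  for (try in 1:500) {
    draw <- lapply(nm, function(f) {
      sd_f <- if (f %in% names(s)) s[[f]] else 0
      if (f == "v_word")
        m[[f]] + sd_f * (rho * z_vocab + sqrt(1 - rho^2) * stats::rnorm(1))
      else
        m[[f]] + sd_f * stats::rnorm(1)
    })
    names(draw) <- nm
    p <- tryCatch(do.call(diffusion_params, draw), error = function(e) NULL)
    if (!is.null(p)) return(list(params = p, vocabulary = vocab))
  }
  stop("could not draw parameters satisfying the invariants; ",
       "check the profile's means and SDs")
}

#' Generate a synthetic cohort
#'
#' Produces a complete synthetic experiment: a stimulus schedule for the
#' design, per-participant true parameters and vocabulary scores drawn from
#' the group profiles, diffusion-simulated responses and RTs for every
#' non-reference item (optionally contaminated), and a digital-pen stroke
#' log constructed so that [strokes_to_trials()] inverts it exactly. RTs are
#' quantised to 1 ms, the timestamp resolution of the emulated pen
#' hardware; the returned trial table is itself derived from the stroke log,
#' so the stroke/trial round trip is an identity by construction.
#'
#' @param profiles A list of [group_profile()] objects.
#' @param design An [experiment_design()].
#' @param seed Optional seed.
#' @param dt Euler step for the trial simulator (seconds).
#' @return A list with `strokes`, `trials`, `truth` (per-participant group,
#'   true parameters, vocabulary, trial counts) and `schedule`.
#' @examples
#' \donttest{
#' coh <- generate_cohort(list(group_profile("younger", n_participants = 2)),
#'                        experiment_design(n_sessions = 4,
#'                                          n_practice_sessions = 1),
#'                        seed = 1)
#' table(coh$trials$condition)
#' }
#' @export
generate_cohort <- function(profiles, design = experiment_design(),
                            seed = NULL, dt = 2e-4) {
  if (inherits(profiles, "group_profile")) profiles <- list(profiles)
  stopifnot(length(profiles) >= 1)
  if (!is.null(seed)) set.seed(seed)
  schedule <- build_design(design)
  nonref <- schedule[!schedule$is_reference, ]

  strokes_all <- vector("list", 0)
  truth_rows <- vector("list", 0)
  for (profile in profiles) {
    for (i in seq_len(profile$n_participants)) {
      pid <- sprintf("%s_%02d", profile$label, i)
      truth <- draw_participant_truth(profile)
      sim <- simulate_schedule_responses(truth$params, nonref,
                                         profile$contamination_rate, dt)
      strokes <- responses_to_strokes(pid, schedule, sim)
      strokes_all[[length(strokes_all) + 1]] <- strokes
      truth_rows[[length(truth_rows) + 1]] <- data.frame(
        participant_id = pid, group = profile$label,
        vocabulary = truth$vocabulary,
        as.data.frame(unclass(truth$params)[c("v_word", "v_nonword", "a",
                                              "zr_word", "zr_nonword", "t0",
                                              "s_v", "s_zr", "s_t0")]),
        n_word = sum(nonref$condition == "word"),
        n_nonword = sum(nonref$condition == "nonword"),
        stringsAsFactors = FALSE)
    }
  }
  strokes <- do.call(rbind, strokes_all)
  rownames(strokes) <- NULL
  truth <- do.call(rbind, truth_rows)
  rownames(truth) <- NULL
  trials <- strokes_to_trials(strokes, schedule,
                              n_practice_sessions = design$n_practice_sessions)
  list(strokes = strokes, trials = trials, truth = truth, schedule = schedule)
}

## simulate responses/RTs for the non-reference items of one participant;
## RTs are quantised to 1 ms
simulate_schedule_responses <- function(params, nonref, contamination_rate, dt) {
  out <- data.frame(session = nonref$session, page = nonref$page,
                    slot = nonref$slot, condition = nonref$condition,
                    response = NA_character_, rt = NA_real_,
                    stringsAsFactors = FALSE)
  for (cond in c("word", "nonword")) {
    idx <- which(out$condition == cond)
    if (!length(idx)) next
    sim <- simulate_trials(length(idx), params, cond, dt = dt)
    out$response[idx] <- ifelse(sim$response == "upper", "word", "nonword")
    out$rt[idx] <- sim$rt
  }
  if (contamination_rate > 0) {
    contam <- stats::runif(nrow(out)) < contamination_rate
    n_c <- sum(contam)
    if (n_c > 0) {
      out$rt[contam] <- stats::runif(n_c, 0.25, 3.5)
      out$response[contam] <- sample(c("word", "nonword"), n_c, replace = TRUE)
    }
  }
  out$rt <- round(out$rt, 3)
  out
}

## synthesise a stroke log whose stroke-difference RTs equal the simulated
## RTs; timestamps are integer milliseconds since page start
responses_to_strokes <- function(pid, schedule, sim) {
  key <- paste(sim$session, sim$page, sim$slot)
  skey <- paste(schedule$session, schedule$page, schedule$slot)
  idx <- match(skey, key)
  response <- sim$response[idx]
  rt_ms <- round(sim$rt[idx] * 1000)
  # references (slot 1): treat as answered correctly, no RT involved
  ref <- schedule$slot == 1L
  response[ref] <- schedule$condition[ref]
  checkbox <- ifelse(response == "word", "yes", "no")

  ord <- order(schedule$session, schedule$page, schedule$slot)
  pen_down_ms <- pen_up_ms <- integer(nrow(schedule))
  stroke_dur_ms <- 400L
  page_id <- paste(schedule$session, schedule$page)
  t_cursor <- 0L
  last_page <- ""
  for (r in ord) {
    if (page_id[r] != last_page) {
      t_cursor <- 500L              # first stroke starts 0.5 s into the page
      last_page <- page_id[r]
      pen_down_ms[r] <- t_cursor
    } else {
      pen_down_ms[r] <- t_cursor + as.integer(rt_ms[r])
    }
    pen_up_ms[r] <- pen_down_ms[r] + stroke_dur_ms
    t_cursor <- pen_up_ms[r]
  }
  data.frame(participant_id = pid, session = schedule$session,
             page = schedule$page, slot = schedule$slot,
             checkbox = checkbox,
             pen_down = pen_down_ms / 1000, pen_up = pen_up_ms / 1000,
             stringsAsFactors = FALSE)
}

#' @rdname table_io
#' @param truth A cohort truth table from [generate_cohort()].
#' @export
write_truth <- function(truth, path) {
  utils::write.csv(truth, path, row.names = FALSE, quote = FALSE)
  invisible(truth)
}

#' @rdname table_io
#' @export
read_truth <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
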