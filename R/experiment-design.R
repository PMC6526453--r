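#' Paper-based lexical decision experiment design
#'
#' Describes the structure of a paper-based lexical decision experiment
#' administered with digital pens: sessions of several printed pages, each
#' page holding a column of letter-string stimuli with yes/no checkboxes.
#' The first stimulus on every page is a *reference* item: it anchors the
#' response-time computation for the page and is excluded from analysis.
#'
#' @param n_sessions Number of sessions.
#' @param pages_per_session Pages per session.
#' @param items_per_page Stimuli per page (including the reference).
#' @param n_practice_sessions Leading sessions flagged as practice.
#' @param words_per_session,nonwords_per_session Non-reference words and
#'   nonwords per session; their sum must equal
#'   `pages_per_session * (items_per_page - 1)`.
#' @param word_length_range Inclusive range of word lengths in letters.
#' @param low_frequency_proportion Fraction of words labelled low-frequency
#'   (the rest are very-low-frequency).
#'
#' @return An object of class `experiment_design`.
#' @examples
#' d <- experiment_design()
#' d$n_sessions * d$pages_per_session * d$items_per_page  # total stimuli
#' @export
experiment_design <- function(n_sessions = 67, pages_per_session = 3,
                              items_per_page = 11, n_practice_sessions = 2,
                              words_per_session = 15, nonwords_per_session = 15,
                              word_length_range = c(5, 7),
                              low_frequency_proportion = 0.467) {
  d <- list(n_sessions = as.integer(n_sessions),
            pages_per_session = as.integer(pages_per_session),
            items_per_page = as.integer(items_per_page),
            n_practice_sessions = as.integer(n_practice_sessions),
            words_per_session = as.integer(words_per_session),
            nonwords_per_session = as.integer(nonwords_per_session),
            word_length_range = as.integer(word_length_range),
            low_frequency_proportion = low_frequency_proportion)
  if (d$items_per_page < 2) stop("items_per_page must be at least 2")
  if (d$words_per_session + d$nonwords_per_session !=
      d$pages_per_session * (d$items_per_page - 1))
    stop("words_per_session + nonwords_per_session must equal ",
         "pages_per_session * (items_per_page - 1)")
  if (d$n_practice_sessions >= d$n_sessions)
    stop("n_practice_sessions must be smaller than n_sessions")
  if (low_frequency_proportion < 0 || low_frequency_proportion > 1)
    stop("low_frequency_proportion must be in [0, 1]")
  if (length(d$word_length_range) != 2 || diff(d$word_length_range) < 0)
    stop("word_length_range must be an increasing length-2 vector")
  class(d) <- "experiment_design"
  d
}

#' @export
print.experiment_design <- function(x, ...) {
  total <- x$n_sessions * x$pages_per_session * x$items_per_page
  cat("Paper-based lexical decision design:\n",
      x$n_sessions, "sessions x", x$pages_per_session, "pages x",
      x$items_per_page, "items =", total, "stimuli (",
      x$n_sessions * x$pages_per_session, "references)\n")
  invisible(x)
}

VOWELS <- c("a", "e", "i", "o", "u")
UMLAUTS <- c("\u00e4", "\u00f6", "\u00fc")   # a/o/u umlauts

#' Turn a word into a nonword by vowel replacement
#'
#' Every vowel is replaced by a randomly chosen *different* plain vowel;
#' consonants keep their positions. Two exceptions follow German
#' orthography: a `u` immediately after a `q` is left unchanged, and
#' umlauts are treated as vowels but always replaced by non-umlaut vowels.
#' Case is preserved. A vowel-free input is returned unchanged.
#'
#' @param word A letter string.
#' @return A nonword string of the same length.
#' @examples
#' set.seed(1)
#' make_nonword("Miete")
#' make_nonword("Quark")   # the 'u' stays
#' @export
make_nonword <- function(word) {
  stopifnot(is.character(word), length(word) == 1, nzchar(word))
  ch <- strsplit(word, "")[[1]]
  lo <- tolower(ch)
  for (i in seq_along(ch)) {
    is_vowel <- lo[i] %in% c(VOWELS, UMLAUTS)
    if (!is_vowel) next
    if (lo[i] == "u" && i > 1 && lo[i - 1] == "q") next
    cand <- setdiff(VOWELS, lo[i])
    repl <- sample(cand, 1)
    if (ch[i] != lo[i]) repl <- toupper(repl)
    ch[i] <- repl
  }
  paste(ch, collapse = "")
}

#' Generate a placeholder stimulus pool
#'
#' Builds `n_words` pronounceable-looking placeholder words (random
#' consonant-vowel alternating strings, not real German) with lengths
#' uniform over the design's word-length range, labels a fraction of them
#' low-frequency (the rest very-low-frequency), and derives one nonword per
#' word via [make_nonword()].
#'
#' @param n_words Number of words (>= 1).
#' @param design An [experiment_design()] (supplies length range and
#'   frequency-class proportion).
#' @return A data frame with columns `word`, `nonword`, `frequency_class`.
#' @examples
#' set.seed(1)
#' head(generate_stimulus_pool(5, experiment_design()))
#' @export
generate_stimulus_pool <- function(n_words, design = experiment_design()) {
  stopifnot(n_words >= 1)
  consonants <- setdiff(letters, c(VOWELS, "q"))  # avoid the q-u special case
  lens <- sample(seq(design$word_length_range[1], design$word_length_range[2]),
                 n_words, replace = TRUE)
  words <- vapply(lens, function(L) {
    start_c <- sample(c(TRUE, FALSE), 1)
    ch <- character(L)
    for (i in seq_len(L)) {
      use_c <- xor(i %% 2 == 0, start_c)
      ch[i] <- if (use_c) sample(consonants, 1) else sample(VOWELS, 1)
    }
    paste(ch, collapse = "")
  }, character(1))
  n_low <- round(design$low_frequency_proportion * n_words)
  freq <- sample(rep(c("low", "very_low"), c(n_low, n_words - n_low)))
  nonwords <- vapply(words, make_nonword, character(1), USE.NAMES = FALSE)
  data.frame(word = words, nonword = nonwords, frequency_class = freq,
             stringsAsFactors = FALSE)
}

#' Build the full stimulus schedule
#'
#' Lays out the experiment: for every session, the configured numbers of
#' words and nonwords are assigned (without replacement from the pool) and
#' randomised across the session's pages; slot 1 of every page receives a
#' reference stimulus drawn randomly from the scheduled items.
#'
#' @param design An [experiment_design()].
#' @param pool Optional stimulus pool from [generate_stimulus_pool()]; by
#'   default a pool of exactly the required size is generated.
#' @return The schedule: a data frame with one row per printed stimulus and
#'   columns `stimulus_id`, `text`, `condition`, `frequency_class`,
#'   `session`, `page`, `slot`, `is_reference`.
#' @examples
#' set.seed(1)
#' sched <- build_design(experiment_design(n_sessions = 3,
#'   n_practice_sessions = 1))
#' nrow(sched)       # 3 * 3 * 11
#' sum(sched$is_reference)
#' @export
build_design <- function(design = experiment_design(), pool = NULL) {
  n_words_needed <- design$n_sessions * design$words_per_session
  n_nonwords_needed <- design$n_sessions * design$nonwords_per_session
  if (is.null(pool))
    pool <- generate_stimulus_pool(max(n_words_needed, n_nonwords_needed), design)
  if (nrow(pool) < max(n_words_needed, n_nonwords_needed))
    stop("stimulus pool too small for this design")

  word_idx <- sample(nrow(pool), n_words_needed)
  nonword_idx <- sample(nrow(pool), n_nonwords_needed)
  items <- rbind(
    data.frame(text = pool$word[word_idx], condition = "word",
               frequency_class = pool$frequency_class[word_idx],
               stringsAsFactors = FALSE),
    data.frame(text = pool$nonword[nonword_idx], condition = "nonword",
               frequency_class = "none", stringsAsFactors = FALSE))
  # session assignment: each session gets its quota of words and nonwords
  items$session <- c(rep(seq_len(design$n_sessions),
                         each = design$words_per_session),
                     rep(seq_len(design$n_sessions),
                         each = design$nonwords_per_session))

  per_page <- design$items_per_page - 1L
  rows <- vector("list", design$n_sessions)
  n_ref_total <- design$n_sessions * design$pages_per_session
  ref_src <- items[sample(nrow(items), n_ref_total), ]
  ref_row <- 0L
  for (s in seq_len(design$n_sessions)) {
    sess <- items[items$session == s, ]
    sess <- sess[sample(nrow(sess)), ]              # randomised order
    sess$page <- rep(seq_len(design$pages_per_session), each = per_page)
    sess$slot <- rep(seq_len(per_page) + 1L, design$pages_per_session)
    sess$is_reference <- FALSE
    refs <- ref_src[ref_row + seq_len(design$pages_per_session), ]
    ref_row <- ref_row + design$pages_per_session
    refs$session <- s
    refs$page <- seq_len(design$pages_per_session)
    refs$slot <- 1L
    refs$is_reference <- TRUE
    rows[[s]] <- rbind(refs, sess)
  }
  sched <- do.call(rbind, rows)
  sched <- sched[order(sched$session, sched$page, sched$slot), ]
  sched$stimulus_id <- sprintf("stim_%05d", seq_len(nrow(sched)))
  rownames(sched) <- NULL
  sched <- sched[, c("stimulus_id", "text", "condition", "frequency_class",
                     "session", "page", "slot", "is_reference")]
  attr(sched, "design") <- design
  sched
}

#' Derive trial records from pen stroke logs
#'
#' Item-level response times are computed from time differences between the
#' strokes of consecutive responses on a page: the RT of the item in slot
#' `i >= 2` is the pen-down time of its checkmark minus the pen-up time of
#' the previous item's checkmark. Slot 1 is the page's reference item and
#' yields no RT. A missing stroke breaks the chain: the missing item's
#' response is recorded as missing and the *following* item's RT is also
#' unavailable (RTs are never computed across gaps).
#'
#' @param strokes Stroke log data frame with columns `participant_id`,
#'   `session`, `page`, `slot`, `checkbox` (`"yes"`/`"no"`), `pen_down`,
#'   `pen_up` (seconds since page start).
#' @param schedule A schedule from [build_design()].
#' @param n_practice_sessions Sessions flagged `is_practice` (defaults to
#'   the schedule's design, if attached, else 2).
#' @return Trial records: one row per participant and scheduled stimulus
#'   with columns `participant_id`, `session`, `page`, `slot`, `condition`,
#'   `is_reference`, `is_practice`, `response`, `rt`, `correct`.
#' @export
strokes_to_trials <- function(strokes, schedule, n_practice_sessions = NULL) {
  req <- c("participant_id", "session", "page", "slot", "checkbox",
           "pen_down", "pen_up")
  if (!all(req %in% names(strokes)))
    stop("strokes must have columns: ", paste(req, collapse = ", "))
  if (any(strokes$pen_up < strokes$pen_down))
    stop("stroke with pen_up before pen_down")
  if (is.null(n_practice_sessions)) {
    d <- attr(schedule, "design")
    n_practice_sessions <- if (!is.null(d)) d$n_practice_sessions else 2L
  }
  skey <- paste(schedule$session, schedule$page, schedule$slot)
  out <- vector("list", 0)
  for (pid in unique(strokes$participant_id)) {
    st <- strokes[strokes$participant_id == pid, ]
    kkey <- paste(st$session, st$page, st$slot)
    if (anyDuplicated(kkey))
      stop("duplicate stroke for participant ", pid)
    idx <- match(skey, kkey)
    pen_down <- st$pen_down[idx]
    pen_up <- st$pen_up[idx]
    checkbox <- st$checkbox[idx]
    response <- ifelse(is.na(checkbox), NA_character_,
                       ifelse(checkbox == "yes", "word", "nonword"))
    # previous slot on the same page
    prev_key <- paste(schedule$session, schedule$page, schedule$slot - 1L)
    prev_idx <- match(prev_key, kkey)
    prev_pen_up <- st$pen_up[prev_idx]
    rt <- pen_down - prev_pen_up
    rt[schedule$slot == 1L] <- NA_real_          # references carry no RT
    bad <- which(!is.na(rt) & rt < 0)
    if (length(bad))
      stop("negative RT for participant ", pid, " at session ",
           schedule$session[bad[1]], " page ", schedule$page[bad[1]],
           " slot ", schedule$slot[bad[1]])
    tr <- data.frame(participant_id = pid,
                     session = schedule$session,
                     page = schedule$page,
                     slot = schedule$slot,
                     condition = schedule$condition,
                     is_reference = schedule$is_reference,
                     is_practice = schedule$session <= n_practice_sessions,
                     response = response,
                     rt = rt,
                     stringsAsFactors = FALSE)
    out[[length(out) + 1]] <- tr
  }
  trials <- do.call(rbind, out)
  trials$correct <- ifelse(is.na(trials$response), NA,
                           trials$response == trials$condition)
  rownames(trials) <- NULL
  trials
}

#' Trim implausible response times
#'
#' Eliminates non-reference trials whose RT falls outside `[lo, hi]`
#' (inclusive); the default window keeps 250 ms to 3500 ms. Reference rows
#' and rows without an RT are untouched.
#'
#' @param trials Trial records (see [strokes_to_trials()]).
#' @param lo,hi Window bounds in seconds, `lo < hi`.
#' @return A list with `trials` (the kept records), `n_eliminated`, and
#'   `fraction_eliminated` (relative to the non-reference trials that
#'   carried an RT).
#' @examples
#' tr <- data.frame(participant_id = "p1", session = 1, page = 1, slot = 2:5,
#'                  condition = "word", is_reference = FALSE,
#'                  is_practice = FALSE, response = "word",
#'                  rt = c(0.2, 0.3, 3.6, 1.0), correct = TRUE)
#' trim_rts(tr)$n_eliminated
#' @export
trim_rts <- function(trials, lo = 0.250, hi = 3.500) {
  stopifnot(lo < hi)
  eligible <- !trials$is_reference & !is.na(trials$rt)
  drop <- eligible & (trials$rt < lo | trials$rt > hi)
  n_elim <- sum(drop)
  list(trials = trials[!drop, , drop = FALSE],
       n_eliminated = n_elim,
       fraction_eliminated = if (sum(eligible) > 0) n_elim / sum(eligible) else 0)
}

## ---- file dialects --------------------------------------------------------

fmt_num <- function(x) {
  out <- formatC(x, format = "g", digits = 17)
  out[is.na(x)] <- "NA"
  out
}

read_checked_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  df
}

num_col <- function(df, col, path, allow_na = FALSE) {
  raw <- df[[col]]
  val <- suppressWarnings(as.numeric(raw))
  # read.csv already turns literal "NA" into NA_character_
  bad <- is.na(val) & !(allow_na & (is.na(raw) | raw %in% c("NA", "")))
  if (any(bad))
    stop("parse error in ", path, " line ", which(bad)[1] + 1,
         ": non-numeric value '", raw[which(bad)[1]], "' in column '", col, "'")
  val
}

#' Read and write stroke-log, trial, and schedule tables
#'
#' Plain CSV dialects (UTF-8, '.' decimal, header required) for the three
#' tables the pipeline exchanges: stroke logs
#' (`participant_id, session, page, slot, checkbox, pen_down_s, pen_up_s`),
#' trial tables (`..., condition, is_reference, is_practice, response, rt_s`)
#' and schedules. Writing then reading is the identity on records; malformed
#' numeric fields raise a parse error naming the line.
#'
#' @param strokes,trials,schedule The records to write.
#' @param path File path.
#' @return The records (invisibly for writers).
#' @name table_io
NULL

#' @rdname table_io
#' @export
write_strokes <- function(strokes, path) {
  df <- data.frame(participant_id = strokes$participant_id,
                   session = strokes$session, page = strokes$page,
                   slot = strokes$slot, checkbox = strokes$checkbox,
                   pen_down_s = fmt_num(strokes$pen_down),
                   pen_up_s = fmt_num(strokes$pen_up))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(strokes)
}

#' @rdname table_io
#' @export
read_strokes <- function(path) {
  df <- read_checked_csv(path)
  data.frame(participant_id = df$participant_id,
             session = num_col(df, "session", path),
             page = num_col(df, "page", path),
             slot = num_col(df, "slot", path),
             checkbox = df$checkbox,
             pen_down = num_col(df, "pen_down_s", path),
             pen_up = num_col(df, "pen_up_s", path),
             stringsAsFactors = FALSE)
}

#' @rdname table_io
#' @export
write_trials <- function(trials, path) {
  df <- data.frame(participant_id = trials$participant_id,
                   session = trials$session, page = trials$page,
                   slot = trials$slot, condition = trials$condition,
                   is_reference = as.integer(trials$is_reference),
                   is_practice = as.integer(trials$is_practice),
                   response = ifelse(is.na(trials$response), "NA", trials$response),
                   rt_s = fmt_num(trials$rt))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(trials)
}

#' @rdname table_io
#' @export
read_trials <- function(path) {
  df <- read_checked_csv(path)
  tr <- data.frame(participant_id = df$participant_id,
                   session = num_col(df, "session", path),
                   page = num_col(df, "page", path),
                   slot = num_col(df, "slot", path),
                   condition = df$condition,
                   is_reference = num_col(df, "is_reference", path) == 1,
                   is_practice = num_col(df, "is_practice", path) == 1,
                   response = ifelse(df$response %in% c("NA", ""),
                                     NA_character_, df$response),
                   rt = num_col(df, "rt_s", path, allow_na = TRUE),
                   stringsAsFactors = FALSE)
  tr$correct <- ifelse(is.na(tr$response), NA, tr$response == tr$condition)
  tr
}

#' @rdname table_io
#' @export
write_schedule <- function(schedule, path) {
  df <- schedule
  df$is_reference <- as.integer(df$is_reference)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(schedule)
}

#' @rdname table_io
#' @export
read_schedule <- function(path) {
  df <- read_checked_csv(path)
  data.frame(stimulus_id = df$stimulus_id, text = df$text,
             condition = df$condition, frequency_class = df$frequency_class,
             session = num_col(df, "session", path),
             page = num_col(df, "page", path),
             slot = num_col(df, "slot", path),
             is_reference = num_col(df, "is_reference", path) == 1,
             stringsAsFactors = FALSE)
}
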