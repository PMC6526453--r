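#' Participant-level RT and accuracy summary
#'
#' Summarises trimmed, non-reference trials the way aging studies tabulate
#' them: participant-level accuracy, mean correct RT, mean error RT and
#' observation counts are computed first, then averaged within each group
#' and condition (SDs across participants). A participant without error
#' trials contributes nothing to that cell's error-RT mean. RTs are
#' reported in milliseconds.
#'
#' @param trials Trimmed trial records (several participants).
#' @param groups Data frame mapping `participant_id` to `group`.
#' @return A data frame with one row per group x condition.
#' @export
table2_summary <- function(trials, groups) {
  tr <- trials[!trials$is_reference & !is.na(trials$response) &
                 !is.na(trials$rt), , drop = FALSE]
  tr$group <- groups$group[match(tr$participant_id, groups$participant_id)]
  if (anyNA(tr$group)) stop("some participants have no group label")
  out <- list()
  for (g in unique(groups$group)) {
    for (cond in c("word", "nonword")) {
      tc <- tr[tr$group == g & tr$condition == cond, , drop = FALSE]
      per <- split(tc, tc$participant_id)
      acc <- vapply(per, function(d) mean(d$correct), numeric(1))
      rtc <- vapply(per, function(d) mean(d$rt[d$correct]), numeric(1))
      rte <- vapply(per, function(d)
        if (any(!d$correct)) mean(d$rt[!d$correct]) else NA_real_, numeric(1))
      nobs <- vapply(per, nrow, numeric(1))
      out[[length(out) + 1]] <- data.frame(
        group = g, condition = cond,
        accuracy_mean = mean(acc), accuracy_sd = stats::sd(acc),
        rt_correct_ms_mean = 1000 * mean(rtc),
        rt_correct_ms_sd = 1000 * stats::sd(rtc),
        rt_error_ms_mean = 1000 * mean(rte, na.rm = TRUE),
        rt_error_ms_sd = 1000 * stats::sd(rte, na.rm = TRUE),
        n_obs_mean = mean(nobs), n_obs_sd = stats::sd(nobs),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

test_row <- function(effect, type, value, df1, df2 = NA, eta2 = NA,
                     p_raw = NA, p_adj = NA, n = NA) {
  data.frame(effect = effect, statistic_type = type, value = value,
             df1 = df1, df2 = df2, eta_squared = eta2,
             p_raw = p_raw, p_adjusted = p_adj, n = n,
             stringsAsFactors = FALSE)
}

#' Mixed two-way analysis of variance
#'
#' Classical sums-of-squares decomposition for the balanced 2 (group,
#' between) x 2 (condition, within) mixed design: the group effect is
#' tested against subjects-within-groups, condition and the interaction
#' against the condition x subjects-within-groups error. Effect sizes are
#' partial eta squared, `SS_effect / (SS_effect + SS_error_effect)`.
#'
#' @param data Long data frame with columns `subject`, `group`,
#'   `condition`, `value`; every subject needs both condition values.
#' @return A data frame of three test rows: group, condition, interaction.
#' @export
mixed_anova <- function(data) {
  stopifnot(all(c("subject", "group", "condition", "value") %in% names(data)))
  if (anyNA(data$value)) stop("missing cell value in ANOVA data")
  tab <- table(data$subject, data$condition)
  if (any(tab != 1)) stop("each subject needs exactly one value per condition")
  conds <- sort(unique(data$condition))
  grps <- sort(unique(as.character(data$group)))
  nc <- length(conds)
  if (nc != 2 || length(grps) != 2)
    stop("mixed_anova expects exactly two conditions and two groups")

  gm <- mean(data$value)
  subj_means <- tapply(data$value, data$subject, mean)
  subj_group <- tapply(as.character(data$group), data$subject, function(g) g[1])
  N <- length(subj_means)
  grp_means <- tapply(data$value, data$group, mean)
  n_g <- table(subj_group)[grps]
  cond_means <- tapply(data$value, data$condition, mean)
  cell_means <- tapply(data$value, list(data$group, data$condition), mean)

  ss_between_tot <- nc * sum((subj_means - gm)^2)
  ss_group <- nc * sum(n_g * (grp_means[grps] - gm)^2)
  ss_subj <- ss_between_tot - ss_group
  ss_cond <- N * sum((cond_means - gm)^2)
  ss_inter <- sum(vapply(grps, function(g) {
    sum(vapply(conds, function(cc)
      n_g[[g]] * (cell_means[g, cc] - grp_means[[g]] - cond_means[[cc]] + gm)^2,
      numeric(1)))
  }, numeric(1)))
  within_dev <- data$value - subj_means[as.character(data$subject)]
  ss_within_tot <- sum(within_dev^2)
  ss_err <- ss_within_tot - ss_cond - ss_inter

  df_group <- length(grps) - 1
  df_subj <- N - length(grps)
  df_cond <- nc - 1
  df_err <- df_subj * df_cond
  # all-constant data have zero effect and zero error: define F = 0
  f_ratio <- function(ss_eff, df_eff, ss_err2, df_err2) {
    if (ss_err2 <= 0) return(if (ss_eff <= 0) 0 else Inf)
    (ss_eff / df_eff) / (ss_err2 / df_err2)
  }
  f_group <- f_ratio(ss_group, df_group, ss_subj, df_subj)
  f_cond <- f_ratio(ss_cond, df_cond, ss_err, df_err)
  f_inter <- f_ratio(ss_inter, df_cond, ss_err, df_err)
  rbind(
    test_row("group", "F", f_group, df_group, df_subj,
             ss_group / (ss_group + ss_subj),
             stats::pf(f_group, df_group, df_subj, lower.tail = FALSE), n = N),
    test_row("condition", "F", f_cond, df_cond, df_err,
             ss_cond / (ss_cond + ss_err),
             stats::pf(f_cond, df_cond, df_err, lower.tail = FALSE), n = N),
    test_row("group:condition", "F", f_inter, df_cond, df_err,
             ss_inter / (ss_inter + ss_err),
             stats::pf(f_inter, df_cond, df_err, lower.tail = FALSE), n = N))
}

#' Bonferroni-corrected simple-effect comparisons
#'
#' The follow-up family after a mixed ANOVA: between-group t-tests within
#' each condition (independent, pooled variance) and within-group paired
#' t-tests between conditions. Raw p-values are multiplied by the family
#' size (capped at 1); effect size is `t^2 / (t^2 + df)`.
#'
#' @param data Long data frame as in [mixed_anova()].
#' @param comparisons List of comparisons; each is a list with `type`
#'   (`"between"` or `"within"`) and `condition` (for between) or `group`
#'   (for within). Defaults to all four simple effects.
#' @return A data frame of test rows with adjusted p-values.
#' @export
pairwise_bonferroni <- function(data, comparisons = NULL) {
  if (is.null(comparisons)) {
    conds <- sort(unique(data$condition))
    grps <- sort(unique(as.character(data$group)))
    comparisons <- c(lapply(conds, function(cc) list(type = "between", condition = cc)),
                     lapply(grps, function(g) list(type = "within", group = g)))
  }
  if (!length(comparisons)) stop("empty comparison family")
  m <- length(comparisons)
  rows <- lapply(comparisons, function(cmp) {
    if (cmp$type == "between") {
      d <- data[data$condition == cmp$condition, ]
      grps <- sort(unique(as.character(d$group)))
      tt <- safe_ttest(d$value[d$group == grps[1]],
                       d$value[d$group == grps[2]], paired = FALSE)
      lab <- paste0(grps[1], " vs ", grps[2], " | ", cmp$condition)
      n <- nrow(d)
    } else {
      d <- data[data$group == cmp$group, ]
      conds <- sort(unique(d$condition))
      v1 <- d$value[d$condition == conds[1]][order(d$subject[d$condition == conds[1]])]
      v2 <- d$value[d$condition == conds[2]][order(d$subject[d$condition == conds[2]])]
      tt <- safe_ttest(v1, v2, paired = TRUE)
      lab <- paste0(conds[1], " vs ", conds[2], " | ", cmp$group)
      n <- length(v1)
    }
    t_val <- unname(tt$statistic)
    df <- unname(tt$parameter)
    eta2 <- if (is.finite(t_val)) t_val^2 / (t_val^2 + df) else 1
    test_row(lab, "t", t_val, df, NA, eta2,
             tt$p.value, min(1, tt$p.value * m), n)
  })
  do.call(rbind, rows)
}

## t.test that degrades gracefully on zero-variance input: a zero mean
## difference gives t = 0 (p = 1), a nonzero one t = +-Inf (p = 0)
safe_ttest <- function(v1, v2, paired) {
  tryCatch(stats::t.test(v1, v2, paired = paired, var.equal = !paired),
           error = function(e) {
             md <- mean(v1) - mean(v2)
             df <- if (paired) length(v1) - 1 else length(v1) + length(v2) - 2
             list(statistic = if (md == 0) 0 else sign(md) * Inf,
                  parameter = df,
                  p.value = if (md == 0) 1 else 0)
           })
}

#' Between-group t-test
#'
#' Independent two-sample t-test with pooled variance
#' (`df = n1 + n2 - 2`), as used for the parameters held constant across
#' conditions; effect size `t^2 / (t^2 + df)`.
#'
#' @param values Numeric vector (one value per participant).
#' @param groups Group label per participant (two levels).
#' @param effect Label for the output row.
#' @return A one-row test data frame.
#' @export
ttest_between <- function(values, groups, effect = "group difference") {
  grps <- sort(unique(as.character(groups)))
  if (length(grps) != 2) stop("ttest_between needs exactly two groups")
  v1 <- values[groups == grps[1]]; v2 <- values[groups == grps[2]]
  if (length(v1) < 2 || length(v2) < 2) stop("need at least two values per group")
  if (stats::var(v1) + stats::var(v2) == 0)
    stop("degenerate data: zero pooled variance")
  tt <- stats::t.test(v1, v2, var.equal = TRUE)
  t_val <- unname(tt$statistic)
  df <- unname(tt$parameter)
  test_row(effect, "t", t_val, df, NA, t_val^2 / (t_val^2 + df),
           tt$p.value, n = length(values))
}

#' Align nonword drift sign for group comparisons
#'
#' Nonword drift rates are negative (evidence accumulates toward the
#' "nonword" boundary); for ANOVAs on drift magnitude they are multiplied
#' by -1 so that larger values mean better performance in both conditions.
#' Word drifts are unchanged; applying the conversion twice is the
#' identity.
#'
#' @param fits Per-participant fit table (column `v_nonword`).
#' @return The fit table with `v_nonword` sign-flipped.
#' @export
drift_sign_convert <- function(fits) {
  fits$v_nonword <- -fits$v_nonword
  fits
}

#' Vocabulary-drift correlation and age-partialled correlation
#'
#' Pearson correlation between word drift estimates and vocabulary scores,
#' and the partial correlation controlling for the binary age-group
#' indicator via
#' `r_xy.z = (r_xy - r_xz r_yz) / sqrt((1 - r_xz^2)(1 - r_yz^2))`.
#'
#' @param v_word Word drift estimates.
#' @param vocabulary Vocabulary scores.
#' @param group_labels Group label per participant (two levels).
#' @return A list with `r_bivariate`, `r_partial`, their p-values, and `n`.
#' @export
correlations <- function(v_word, vocabulary, group_labels) {
  n <- length(v_word)
  stopifnot(length(vocabulary) == n, length(group_labels) == n, n >= 4)
  if (stats::var(v_word) == 0 || stats::var(vocabulary) == 0)
    stop("degenerate data: zero variance")
  z <- as.numeric(factor(group_labels))
  if (length(unique(z)) < 2) z <- rep(0, n)
  r_xy <- stats::cor(v_word, vocabulary)
  if (stats::var(z) > 0) {
    r_xz <- stats::cor(v_word, z)
    r_yz <- stats::cor(vocabulary, z)
    r_p <- (r_xy - r_xz * r_yz) / sqrt((1 - r_xz^2) * (1 - r_yz^2))
  } else {
    r_p <- r_xy
  }
  p_of_r <- function(r, df) 2 * stats::pt(-abs(r * sqrt(df / (1 - r^2))), df)
  list(r_bivariate = r_xy, p_bivariate = p_of_r(r_xy, n - 2),
       r_partial = r_p, p_partial = p_of_r(r_p, n - 3), n = n)
}

#' Full group-level analysis
#'
#' Runs the statistical stage on a fitted cohort: RT/accuracy summaries,
#' mixed ANOVAs (with the four simple-effect follow-ups) for correct RT,
#' accuracy, drift rate (nonword sign aligned) and relative starting point,
#' between-group t-tests for boundary separation, nondecision time and the
#' variability parameters, and the vocabulary-drift correlations.
#'
#' @param trials Trimmed trial records.
#' @param fits Per-participant fit table ([fit_cohort()]).
#' @param truth Participant table with `participant_id`, `group` and
#'   (optionally) `vocabulary`.
#' @param exclude Participant ids to drop (e.g. flagged misfits) before
#'   testing.
#' @return A list with `summary` (group x condition table), `effects` (all
#'   test rows) and `correlations`.
#' @export
group_analysis <- function(trials, fits, truth, exclude = NULL) {
  keep <- !(fits$participant_id %in% exclude) & fits$converged
  fits <- fits[keep, , drop = FALSE]
  trials <- trials[trials$participant_id %in% fits$participant_id, , drop = FALSE]
  groups <- truth[, c("participant_id", "group")]

  summary_tab <- table2_summary(trials, groups)

  tr <- trials[!trials$is_reference & !is.na(trials$response) &
                 !is.na(trials$rt), , drop = FALSE]
  tr$group <- groups$group[match(tr$participant_id, groups$participant_id)]
  long_rt <- stats::aggregate(rt ~ participant_id + group + condition,
                              data = tr[tr$correct, ], FUN = mean)
  names(long_rt) <- c("subject", "group", "condition", "value")
  long_acc <- stats::aggregate(correct ~ participant_id + group + condition,
                               data = tr, FUN = mean)
  names(long_acc) <- c("subject", "group", "condition", "value")

  fitsc <- drift_sign_convert(fits)
  grp_of <- groups$group[match(fits$participant_id, groups$participant_id)]
  long_v <- data.frame(
    subject = rep(fits$participant_id, 2),
    group = rep(grp_of, 2),
    condition = rep(c("word", "nonword"), each = nrow(fits)),
    value = c(fitsc$v_word, fitsc$v_nonword), stringsAsFactors = FALSE)
  long_zr <- data.frame(
    subject = rep(fits$participant_id, 2),
    group = rep(grp_of, 2),
    condition = rep(c("word", "nonword"), each = nrow(fits)),
    value = c(fits$zr_word, fits$zr_nonword), stringsAsFactors = FALSE)

  effects <- list()
  for (measure in c("correct_rt", "accuracy", "drift", "starting_point")) {
    d <- switch(measure, correct_rt = long_rt, accuracy = long_acc,
                drift = long_v, starting_point = long_zr)
    an <- mixed_anova(d)
    an$effect <- paste0(measure, ": ", an$effect)
    fu <- pairwise_bonferroni(d)
    fu$effect <- paste0(measure, ": ", fu$effect)
    effects[[length(effects) + 1]] <- rbind(an, fu)
  }
  for (par in c("a", "t0", "s_v", "s_zr", "s_t0")) {
    lab <- paste0(par, ": group difference")
    effects[[length(effects) + 1]] <- tryCatch(
      ttest_between(fits[[par]], grp_of, effect = lab),
      # e.g. variabilities fixed at zero during fitting: no comparison
      error = function(e) test_row(lab, "t", NA_real_, NA, n = nrow(fits)))
  }
  effects <- do.call(rbind, effects)
  rownames(effects) <- NULL

  corr <- NULL
  if ("vocabulary" %in% names(truth)) {
    vocab <- truth$vocabulary[match(fits$participant_id, truth$participant_id)]
    corr <- correlations(fits$v_word, vocab, grp_of)
  }
  list(summary = summary_tab, effects = effects, correlations = corr)
}
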