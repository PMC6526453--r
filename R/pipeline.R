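#' Pipeline configuration
#'
#' Bundles everything one end-to-end run needs: the experiment design, the
#' synthetic group profiles, the fitting and diagnostics configuration, the
#' trimming window, the output directory, a master seed and the stages to
#' execute. Per-stage child seeds are derived deterministically from the
#' master seed, so a fixed seed makes the full run reproducible.
#'
#' @param out_dir Output directory (created if needed).
#' @param design An [experiment_design()].
#' @param profiles List of [group_profile()]s for the simulate stage.
#' @param fit A [fit_config()].
#' @param n_sims,alpha Bootstrap calibration settings for the assess stage.
#' @param trim_lo,trim_hi RT trimming window (seconds).
#' @param seed Master seed.
#' @param stages Character vector drawn from
#'   `c("simulate", "preprocess", "fit", "assess", "stats")`.
#' @param exclude_flagged Rerun the stats stage without participants
#'   flagged by the calibrated fit criterion.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir,
                            design = experiment_design(),
                            profiles = list(group_profile("younger"),
                                            group_profile("older")),
                            fit = fit_config(),
                            n_sims = 1000, alpha = 0.01,
                            trim_lo = 0.25, trim_hi = 3.5,
                            seed = 1L,
                            stages = c("simulate", "preprocess", "fit",
                                       "assess", "stats"),
                            exclude_flagged = FALSE) {
  stages <- match.arg(stages, several.ok = TRUE)
  stopifnot(trim_lo < trim_hi, n_sims >= 1)
  structure(list(out_dir = out_dir, design = design, profiles = profiles,
                 fit = fit, n_sims = n_sims, alpha = alpha,
                 trim_lo = trim_lo, trim_hi = trim_hi,
                 seed = as.integer(seed), stages = stages,
                 exclude_flagged = exclude_flagged),
            class = "pipeline_config")
}

stage_seed <- function(config, stage) {
  config$seed + 1000L * match(stage, c("simulate", "preprocess", "fit",
                                       "assess", "stats"))
}

#' Run the analysis pipeline
#'
#' Executes the enabled stages in order — simulate a cohort, preprocess
#' stroke logs into trimmed trials, fit every participant, calibrate the
#' fit criterion and flag misfits, and run the group statistics — writing
#' each stage's artifacts into the output directory together with a run log
#' and a manifest. A failing stage aborts the run with the stage named and
#' leaves a `FAILED` marker; artifacts of completed stages are retained.
#'
#' @param config A [pipeline_config()].
#' @return The manifest: a list mapping stage names to the files written
#'   (also saved as `manifest.json`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  failed_marker <- file.path(out, "FAILED")
  if (file.exists(failed_marker)) unlink(failed_marker)
  log_path <- file.path(out, "run.log")
  cat("", file = log_path)
  manifest <- list()
  log_line <- function(...) {
    msg <- paste0(format(Sys.time(), "%Y-%m-%d %H:%M:%S "), sprintf(...))
    cat(msg, "\n", file = log_path, append = TRUE, sep = "")
    message(msg)
  }
  run_stage <- function(stage, fun) {
    t0 <- Sys.time()
    res <- tryCatch(fun(), error = function(e) {
      cat("FAILED in stage:", stage, "\n", conditionMessage(e), "\n",
          file = failed_marker)
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    dur <- round(as.numeric(Sys.time() - t0, units = "secs"), 2)
    log_line("stage %s done in %.2f s (seed %d)", stage, dur,
             stage_seed(config, stage))
    manifest[[stage]] <<- res
    res
  }
  path <- function(f) file.path(out, f)

  if ("simulate" %in% config$stages) {
    run_stage("simulate", function() {
      coh <- generate_cohort(config$profiles, config$design,
                             seed = stage_seed(config, "simulate"))
      write_strokes(coh$strokes, path("strokes.csv"))
      write_schedule(coh$schedule, path("schedule.csv"))
      write_truth(coh$truth, path("truth.csv"))
      c("strokes.csv", "schedule.csv", "truth.csv")
    })
  }
  if ("preprocess" %in% config$stages) {
    run_stage("preprocess", function() {
      need(path("strokes.csv"), "preprocess", "simulate")
      strokes <- read_strokes(path("strokes.csv"))
      schedule <- read_schedule(path("schedule.csv"))
      trials <- strokes_to_trials(strokes, schedule,
                                  config$design$n_practice_sessions)
      tr <- trim_rts(trials, config$trim_lo, config$trim_hi)
      log_line("trimming eliminated %d of %d RTs (%.2f%%)",
               tr$n_eliminated,
               tr$n_eliminated + sum(!tr$trials$is_reference & !is.na(tr$trials$rt)),
               100 * tr$fraction_eliminated)
      write_trials(tr$trials, path("trials.csv"))
      "trials.csv"
    })
  }
  if ("fit" %in% config$stages) {
    run_stage("fit", function() {
      need(path("trials.csv"), "fit", "preprocess")
      trials <- read_trials(path("trials.csv"))
      fits <- fit_cohort(trials, config$fit,
                         seed = stage_seed(config, "fit"))
      write_fits(fits, path("fits.csv"))
      "fits.csv"
    })
  }
  if ("assess" %in% config$stages) {
    run_stage("assess", function() {
      need(path("fits.csv"), "assess", "fit")
      fits <- read_fits(path("fits.csv"))
      cal <- bootstrap_critical_p(fits, config$fit, n_sims = config$n_sims,
                                  alpha = config$alpha,
                                  trim_lo = config$trim_lo,
                                  trim_hi = config$trim_hi,
                                  seed = stage_seed(config, "assess"))
      jsonlite::write_json(
        list(alpha = cal$alpha, critical_p = cal$critical_p,
             n_sims = cal$n_sims,
             simulated_p_quantiles = as.list(stats::quantile(
               cal$simulated_p, c(0.01, 0.05, 0.25, 0.5, 0.75, 0.95)))),
        path("calibration.json"), auto_unbox = TRUE, digits = NA)
      flags <- flag_misfit(fits, cal$critical_p)
      utils::write.csv(flags, path("flags.csv"), row.names = FALSE,
                       quote = FALSE)
      log_line("calibrated critical p = %.4f; %d flagged",
               cal$critical_p, attr(flags, "n_flagged"))
      trials <- read_trials(path("trials.csv"))
      overlays <- overlay_tables(fits, trials)
      utils::write.csv(overlays, path("overlays.csv"), row.names = FALSE,
                       quote = FALSE)
      c("calibration.json", "flags.csv", "overlays.csv")
    })
  }
  if ("stats" %in% config$stages) {
    run_stage("stats", function() {
      need(path("fits.csv"), "stats", "fit")
      need(path("trials.csv"), "stats", "preprocess")
      fits <- read_fits(path("fits.csv"))
      trials <- read_trials(path("trials.csv"))
      truth <- read_truth(path("truth.csv"))
      exclude <- NULL
      if (config$exclude_flagged && file.exists(path("flags.csv"))) {
        flags <- utils::read.csv(path("flags.csv"), stringsAsFactors = FALSE)
        exclude <- flags$participant_id[flags$flagged]
      }
      res <- group_analysis(trials, fits, truth, exclude = exclude)
      utils::write.csv(res$effects, path("results.csv"), row.names = FALSE)
      utils::write.csv(res$summary, path("summary.csv"), row.names = FALSE)
      if (!is.null(res$correlations))
        jsonlite::write_json(res$correlations, path("correlations.json"),
                             auto_unbox = TRUE, digits = NA)
      c("results.csv", "summary.csv",
        if (!is.null(res$correlations)) "correlations.json")
    })
  }

  jsonlite::write_json(manifest, path("manifest.json"), auto_unbox = TRUE)
  manifest
}

need <- function(file, stage, producer) {
  if (!file.exists(file))
    stop("stage '", stage, "' needs ", basename(file),
         " (produced by the '", producer, "' stage)")
  invisible(TRUE)
}

## per-participant, per-condition overlay curves on a decimated grid
overlay_tables <- function(fits, trials, points = 200) {
  rows <- list()
  for (i in seq_len(nrow(fits))) {
    if (!isTRUE(fits$converged[i])) next
    est <- do.call(diffusion_params, as.list(fits[i, c(
      "v_word", "v_nonword", "a", "zr_word", "zr_nonword",
      "t0", "s_v", "s_zr", "s_t0")]))
    fit <- list(estimate = est, converged = TRUE)
    tr <- trials[trials$participant_id == fits$participant_id[i], ]
    for (cond in c("word", "nonword")) {
      s <- signed_sample(tr, cond)
      grid <- stats::quantile(s$values, seq(0.005, 0.995, length.out = points),
                              type = 1, names = FALSE)
      ov <- cdf_overlay_table(fit, tr, cond, grid = unique(grid))
      ov <- cbind(participant_id = fits$participant_id[i], condition = cond, ov)
      rows[[length(rows) + 1]] <- ov
    }
  }
  do.call(rbind, rows)
}
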