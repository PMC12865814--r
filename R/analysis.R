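# Behavioural post-processing: trial/run exclusion, learning-curve binning,
# reaction-time/surprise association, and fMRI regressor export.

#' Trial and run exclusion
#'
#' Removes omissions, reaction times under `rt_min` seconds, and (in a
#' single pass) reaction times beyond `sd_mult` standard deviations of the
#' run mean computed on the trials surviving the first two rules.  Runs
#' with more than `max_omission_rate` omissions are flagged for exclusion.
#'
#' @param behaviour an `msl_behaviour` record.
#' @param rt_min minimum reaction time in seconds.
#' @param sd_mult standard-deviation multiplier of the outlier rule.
#' @param max_omission_rate run-level omission threshold (exceeded
#'   strictly).
#' @return list: `data` (surviving trials, original indices kept), `log`
#'   (data frame of excluded trials with the rule that removed each),
#'   `run_excluded`, `omission_rate`.
#' @export
#' @examples
#' seq <- design_run(task_config("match_recognition"), seed = 1)
#' beh <- simulate_run(seq, rl_params("simple", eta_c = 0.4),
#'                     ddm_params(2, 2.3, 0.9), seed = 1)
#' filter_trials(beh)$omission_rate
filter_trials <- function(behaviour, rt_min = 0.2, sd_mult = 3,
                          max_omission_rate = 0.2) {
  n <- nrow(behaviour)
  omitted <- is.na(behaviour$response) | is.na(behaviour$rt)
  fast <- !omitted & behaviour$rt < rt_min
  keep1 <- !omitted & !fast
  m <- mean(behaviour$rt[keep1])
  s <- sd(behaviour$rt[keep1])
  outlier <- keep1 & (abs(behaviour$rt - m) > sd_mult * s)
  outlier[is.na(outlier)] <- FALSE
  keep <- keep1 & !outlier
  rule <- rep(NA_character_, n)
  rule[omitted] <- "omission"
  rule[fast] <- "rt_min"
  rule[outlier] <- "rt_sd"
  log <- data.frame(trial = behaviour$trial[!keep], rule = rule[!keep],
                    stringsAsFactors = FALSE)
  omission_rate <- mean(omitted)
  list(data = behaviour[keep, , drop = FALSE], log = log,
       run_excluded = omission_rate > max_omission_rate,
       omission_rate = omission_rate)
}

# bin index (1..3) per original trial index: thirds of the run, the last
# bin absorbing the remainder (15/15/14 for 44 trials, 14/14/14 for 42)
bin_index <- function(trial, n_trials) {
  size <- ceiling(n_trials / 3)
  pmin(trial %/% size + 1L, 3L)
}

# response correctness from the sequence's ground truth
score_correct <- function(seq, behaviour) {
  config <- attr(seq, "config")
  if (config$variant == "discriminative_choice") {
    behaviour$response == seq$correct_side
  } else {
    behaviour$response == ifelse(seq$is_match, "match", "nonmatch")
  }
}

#' Learning-curve summaries per run third
#'
#' Splits the run into three bins by original trial index (15/15/14 trials
#' in the discriminative choice task, 14/14/14 in match recognition) and
#' summarises, per bin: mean reaction time of correct surviving trials,
#' accuracy (correct responses / surviving responses) and mean absolute
#' drift rate over all trials of the bin.
#'
#' @param seq,behaviour the run.
#' @param traces optional [run_model()] traces (for the drift summary).
#' @param filtered optional result of [filter_trials()]; computed when
#'   omitted.
#' @return data frame with one row per bin; empty bins give `NA`.
#' @export
bin_summaries <- function(seq, behaviour, traces = NULL, filtered = NULL) {
  config <- attr(seq, "config")
  filtered <- filtered %||% filter_trials(behaviour)
  surv <- filtered$data
  surv$correct <- score_correct(seq[seq$trial %in% surv$trial, , drop = FALSE],
                                surv)
  surv$bin <- bin_index(surv$trial, config$n_trials)
  out <- lapply(1:3, function(b) {
    d <- surv[surv$bin == b, , drop = FALSE]
    acc <- if (nrow(d) > 0) mean(d$correct) else NA_real_
    mrt <- if (any(d$correct)) mean(d$rt[d$correct]) else NA_real_
    drift <- NA_real_
    if (!is.null(traces)) {
      tb <- traces[bin_index(traces$trial, config$n_trials) == b, ]
      drift <- mean(abs(tb$drift))
    }
    data.frame(bin = b, n_trials = nrow(d), accuracy = acc, mean_rt = mrt,
               mean_abs_drift = drift)
  })
  do.call(rbind, out)
}

#' Reaction-time / surprise association
#'
#' Per run, the ordinary-least-squares slope of reaction time on trial-wise
#' surprise over the surviving trials; across runs, a one-sample t-test of
#' the mean slope.  (A deliberate simplification of a full mixed-model
#' analysis: the per-run slopes are the unit of inference.)
#'
#' @param runs either a list of `list(behaviour=, surprise=)` pairs or a
#'   single behaviour record (then `surprise` must be given).
#' @param surprise the run's `msl_surprise` trace (single-run form).
#' @param min_trials minimum surviving trials for a run to enter.
#' @return list: `slopes` data frame (run, slope, se, n; skipped runs are
#'   dropped with a warning) and `test` (t statistic, df, p value, mean
#'   slope) when two or more slopes exist.
#' @export
rt_surprise_association <- function(runs, surprise = NULL, min_trials = 5L) {
  if (!is.null(surprise)) runs <- list(list(behaviour = runs,
                                            surprise = surprise))
  rows <- list()
  for (i in seq_along(runs)) {
    beh <- runs[[i]]$behaviour
    sur <- runs[[i]]$surprise
    surv <- filter_trials(beh)$data
    d <- merge(surv[, c("trial", "rt")], sur[, c("trial", "surprise")],
               by = "trial")
    if (nrow(d) < min_trials) {
      warning("run ", i, " skipped: fewer than ", min_trials,
              " surviving trials")
      next
    }
    if (sd(d$surprise) == 0) {
      warning("run ", i, " skipped: surprise has zero variance")
      next
    }
    fit <- lm(rt ~ surprise, data = d)
    rows[[length(rows) + 1L]] <-
      data.frame(run = i, slope = unname(coef(fit)["surprise"]),
                 se = summary(fit)$coefficients["surprise", "Std. Error"],
                 n = nrow(d))
  }
  slopes <- if (length(rows)) do.call(rbind, rows) else
    data.frame(run = integer(0), slope = numeric(0), se = numeric(0),
               n = integer(0))
  test <- NULL
  if (nrow(slopes) >= 2) {
    tt <- t.test(slopes$slope)
    test <- list(mean_slope = unname(tt$estimate), t = unname(tt$statistic),
                 df = unname(tt$parameter), p = tt$p.value)
  }
  list(slopes = slopes, test = test)
}

#' Export trial-wise fMRI parametric-modulator regressors
#'
#' Builds the first-level event set of one run: stimulus events for ALL
#' trials carrying the surprise modulator (statistical learning is
#' implicit, so no behavioural exclusion applies), feedback events
#' carrying the prediction-error modulator for the trials surviving
#' [filter_trials()], plus two nuisance event sets - feedback onsets of
#' neutral (omission) trials and feedback onsets of RT-outlier trials.
#' Modulators are mean-centred per run over the events that carry them.
#'
#' @param seq,behaviour,traces the run and its model traces.
#' @param surprise the run's surprise trace.
#' @param filtered optional [filter_trials()] result.
#' @param dir optional output directory; when given, writes
#'   `events.tsv` and three-column (onset, duration, weight) timing files
#'   per regressor.
#' @return invisibly, a list with `events` (BIDS-style events table) and
#'   the four regressor data frames.
#' @export
export_regressors <- function(seq, behaviour, traces, surprise,
                              filtered = NULL, dir = NULL) {
  config <- attr(seq, "config")
  if (any(is.na(seq$onset_stimulus)))
    stop("sequence has no onsets; run sample_timing() first", call. = FALSE)
  filtered <- filtered %||% filter_trials(behaviour)
  included <- behaviour$trial %in% filtered$data$trial
  omitted <- is.na(behaviour$response)
  outlier <- !included & !omitted

  sur_mod <- surprise$surprise - mean(surprise$surprise)
  rpe_mod <- traces$RPE[included] - mean(traces$RPE[included])

  stim <- data.frame(onset = seq$onset_stimulus,
                     duration = config$stimulus_duration,
                     weight = sur_mod)
  fb_rpe <- data.frame(onset = seq$onset_feedback[included],
                       duration = rep(config$feedback_duration,
                                      sum(included)),
                       weight = rpe_mod)
  neutral <- data.frame(onset = seq$onset_feedback[omitted],
                        duration = rep(config$feedback_duration,
                                       sum(omitted)),
                        weight = rep(1, sum(omitted)))
  rt_out <- data.frame(onset = seq$onset_feedback[outlier],
                       duration = rep(config$feedback_duration,
                                      sum(outlier)),
                       weight = rep(1, sum(outlier)))

  events <- data.frame(
    onset = c(seq$onset_stimulus, seq$onset_feedback),
    duration = c(rep(config$stimulus_duration, nrow(seq)),
                 rep(config$feedback_duration, nrow(seq))),
    trial_type = rep(c("stimulus", "feedback"), each = nrow(seq)),
    trial = c(seq$trial, seq$trial),
    response = c(behaviour$response, behaviour$response),
    rt = c(behaviour$rt, behaviour$rt),
    surprise = c(sur_mod, rep(NA_real_, nrow(seq))),
    rpe = c(rep(NA_real_, nrow(seq)),
            ifelse(included, traces$RPE - mean(traces$RPE[included]),
                   NA_real_)),
    stringsAsFactors = FALSE
  )
  events <- events[order(events$onset), ]

  out <- list(events = events, stimulus_surprise = stim,
              feedback_rpe = fb_rpe, neutral = neutral,
              rt_outliers = rt_out)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    write.table(events, file.path(dir, "events.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE, na = "n/a")
    for (nm in c("stimulus_surprise", "feedback_rpe", "neutral",
                 "rt_outliers"))
      write.table(out[[nm]], file.path(dir, paste0(nm, ".txt")),
                  sep = "\t", quote = FALSE, row.names = FALSE,
                  col.names = FALSE)
  }
  invisible(out)
}
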