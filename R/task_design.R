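# Task-design generation: trial sequences for the two multisensory
# association-learning task variants, with manipulated pairing frequencies,
# probabilistic feedback reversal and gamma-distributed trial timing.

# timing defaults (seconds): printed means and ranges per variant and group
.timing_defaults <- function(variant, group) {
  if (variant == "discriminative_choice") {
    list(iti_mean = 1.87, iti_range = c(0.76, 3.45),
         isi_mean = 3.45, isi_range = c(2.28, 4.83))
  } else if (group == "adult") {
    list(iti_mean = 2.06, iti_range = c(0.79, 3.39),
         isi_mean = 2.67, isi_range = c(1.11, 4.34))
  } else {
    list(iti_mean = 2.05, iti_range = c(0.76, 3.45),
         isi_mean = 3.28, isi_range = c(2.04, 4.90))
  }
}

#' Task configuration
#'
#' Describes one run of either task variant: the discriminative choice task
#' (4 auditory/tactile x 4 visual stimuli, 44 trials, two symbols shown and
#' the side matching the sound/vibration has to be picked) or the match
#' recognition task (3 x 3 stimuli, 42 trials, a single pair is judged
#' match vs non-match).  Timing defaults are the printed per-variant means
#' and ranges; feedback lasts 1.8 s for children and 2 s for adults, the
#' stimulus always 2 s.
#'
#' @param variant task variant.
#' @param modality sensory pairing of the run.
#' @param group age group; only affects timing defaults and feedback
#'   duration.
#' @param reversal_rate fraction of trials whose feedback valence is
#'   reversed; one of 0, 0.05, 0.10, 0.20.
#' @param iti_mean,iti_range,isi_mean,isi_range inter-trial / inter-stimulus
#'   interval mean and truncation range in seconds; defaults follow the
#'   task variant and group.
#' @param stimulus_duration,feedback_duration event durations in seconds.
#' @return an object of class `msl_config`.
#' @export
#' @examples
#' task_config("match_recognition", group = "adult", reversal_rate = 0.1)
task_config <- function(variant = c("discriminative_choice", "match_recognition"),
                        modality = c("audio_visual", "tactile_visual"),
                        group = c("child", "adult"),
                        reversal_rate = 0.1,
                        iti_mean = NULL, iti_range = NULL,
                        isi_mean = NULL, isi_range = NULL,
                        stimulus_duration = 2,
                        feedback_duration = NULL) {
  variant <- match.arg(variant)
  modality <- match.arg(modality)
  group <- match.arg(group)
  if (!reversal_rate %in% c(0, 0.05, 0.10, 0.20))
    stop("`reversal_rate` must be one of 0, 0.05, 0.10, 0.20", call. = FALSE)
  td <- .timing_defaults(variant, group)
  iti_mean <- iti_mean %||% td$iti_mean
  iti_range <- iti_range %||% td$iti_range
  isi_mean <- isi_mean %||% td$isi_mean
  isi_range <- isi_range %||% td$isi_range
  if (iti_mean <= iti_range[1] || iti_mean >= iti_range[2])
    stop("`iti_mean` must lie strictly inside `iti_range`", call. = FALSE)
  if (isi_mean <= isi_range[1] || isi_mean >= isi_range[2])
    stop("`isi_mean` must lie strictly inside `isi_range`", call. = FALSE)
  dc <- variant == "discriminative_choice"
  cfg <- list(
    variant = variant, modality = modality, group = group,
    n_audio_tactile = if (dc) 4L else 3L,
    n_visual = if (dc) 4L else 3L,
    n_trials = if (dc) 44L else 42L,
    reversal_rate = reversal_rate,
    iti_mean = iti_mean, iti_range = iti_range,
    isi_mean = isi_mean, isi_range = isi_range,
    stimulus_duration = stimulus_duration,
    feedback_duration = feedback_duration %||% if (group == "adult") 2 else 1.8
  )
  structure(cfg, class = "msl_config")
}

#' @export
print.msl_config <- function(x, ...) {
  cat("<msl_config>", x$variant, "/", x$modality, "/", x$group, "\n")
  cat("  trials:", x$n_trials, " stimuli:", x$n_audio_tactile, "x",
      x$n_visual, " reversal rate:", x$reversal_rate, "\n")
  cat(sprintf("  ITI %.2f s [%.2f-%.2f]  ISI %.2f s [%.2f-%.2f]\n",
              x$iti_mean, x$iti_range[1], x$iti_range[2],
              x$isi_mean, x$isi_range[1], x$isi_range[2]))
  invisible(x)
}

at_labels <- function(n) LETTERS[seq_len(n)]
vis_labels <- function(n) as.character(seq_len(n) - 1L)

#' Scheduled pairing frequencies of one run
#'
#' Builds the per-run presentation-count table of audio/tactile x visual
#' stimulus combinations.  In the discriminative choice task the matching
#' symbol is shown on every trial of its sound (11/11) and the non-matching
#' partner follows the cyclic 7/3/1 pattern; in the match recognition task
#' each sound pairs 7 times with its matching visual, 5 times with the
#' frequent and 2 times with the rare non-matching visual.
#'
#' @param config an [task_config()] object.
#' @return class `msl_freq_table`: `counts` (co-occurrence counts of sound
#'   and visual, including the always-present matching symbol),
#'   `trial_counts` (trial-defining counts: per non-matching partner in the
#'   discriminative choice task, identical to `counts` otherwise) and
#'   `matching` (the matching visual per sound).
#' @export
pairing_frequency_table <- function(config) {
  if (!inherits(config, "msl_config")) stop("`config` must be an msl_config")
  n <- config$n_audio_tactile
  if (config$variant == "discriminative_choice") {
    if (n != 4L || config$n_visual != 4L)
      stop("discriminative choice requires 4 x 4 stimuli", call. = FALSE)
    # non-matching partner counts, cyclic over the three other visuals
    tc <- matrix(0L, 4, 4, dimnames = list(at_labels(4), vis_labels(4)))
    tc["A", c("1", "2", "3")] <- c(7L, 3L, 1L)
    tc["B", c("0", "3", "2")] <- c(7L, 3L, 1L)
    tc["C", c("3", "0", "1")] <- c(7L, 3L, 1L)
    tc["D", c("2", "1", "0")] <- c(7L, 3L, 1L)
    counts <- tc
    diag(counts) <- 11L # matching symbol shown on all trials of its sound
  } else {
    if (n != 3L || config$n_visual != 3L)
      stop("match recognition requires 3 x 3 stimuli", call. = FALSE)
    tc <- matrix(0L, 3, 3, dimnames = list(at_labels(3), vis_labels(3)))
    tc["A", ] <- c(7L, 2L, 5L)
    tc["B", ] <- c(5L, 7L, 2L)
    tc["C", ] <- c(2L, 5L, 7L)
    counts <- tc
  }
  matching <- setNames(vis_labels(n), at_labels(n))
  structure(list(counts = counts, trial_counts = tc, matching = matching),
            class = "msl_freq_table")
}

#' Generate a pseudorandom trial sequence
#'
#' Expands the pairing-frequency table into a trial list and shuffles it
#' under the given seed.  In the discriminative choice task the side of the
#' matching symbol is counterbalanced as evenly as the odd per-sound trial
#' counts allow (22 left / 22 right overall).  Feedback reversal and trial
#' timing are added by [schedule_feedback_reversal()] and [sample_timing()]
#' (or in one call by [design_run()]).
#'
#' @param config an [task_config()] object.
#' @param seed integer seed; identical seeds give identical sequences.
#' @return a data frame of class `msl_sequence` with one row per trial.
#' @export
make_trial_sequence <- function(config, seed) {
  ft <- pairing_frequency_table(config)
  tc <- ft$trial_counts
  m <- ft$matching
  with_seed(seed, {
    if (config$variant == "discriminative_choice") {
      at <- rep(rownames(tc), times = rowSums(tc))
      nonmatch <- unlist(lapply(rownames(tc), function(s)
        rep(colnames(tc), times = tc[s, ])), use.names = FALSE)
      # counterbalance: each sound has 11 trials; two sounds get 6 "left"
      six_left <- sample(rownames(tc), 2)
      side <- character(length(at))
      for (s in rownames(tc)) {
        idx <- which(at == s)
        nl <- if (s %in% six_left) 6L else 5L
        lft <- sample(idx, nl)
        side[lft] <- "left"
        side[setdiff(idx, lft)] <- "right"
      }
      ord <- sample.int(length(at))
      at <- at[ord]; nonmatch <- nonmatch[ord]; side <- side[ord]
      match_vis <- unname(m[at])
      seq_df <- data.frame(
        trial = seq_along(at) - 1L,
        audio_tactile = at,
        visual_left = ifelse(side == "left", match_vis, nonmatch),
        visual_right = ifelse(side == "left", nonmatch, match_vis),
        is_match = NA,
        correct_side = side,
        feedback_valid = TRUE,
        onset_stimulus = NA_real_, onset_feedback = NA_real_,
        stringsAsFactors = FALSE
      )
    } else {
      at <- rep(rownames(tc), times = rowSums(tc))
      vis <- unlist(lapply(rownames(tc), function(s)
        rep(colnames(tc), times = tc[s, ])), use.names = FALSE)
      ord <- sample.int(length(at))
      at <- at[ord]; vis <- vis[ord]
      seq_df <- data.frame(
        trial = seq_along(at) - 1L,
        audio_tactile = at,
        visual = vis,
        is_match = vis == unname(m[at]),
        correct_side = NA_character_,
        feedback_valid = TRUE,
        onset_stimulus = NA_real_, onset_feedback = NA_real_,
        stringsAsFactors = FALSE
      )
    }
    structure(seq_df, config = config, seed = seed,
              class = c("msl_sequence", "data.frame"))
  })
}

#' Schedule probabilistic feedback reversal
#'
#' Marks `round(rate * n_trials)` trials (ties rounded up) as
#' `feedback_valid = FALSE`, allocated round-robin across the
#' auditory/tactile stimuli in random order so per-stimulus reversal counts
#' differ by at most one.
#'
#' @param seq an `msl_sequence`.
#' @param rate reversal fraction; one of 0, 0.05, 0.10, 0.20.  Defaults to
#'   the rate in the sequence's configuration.
#' @param seed integer seed.
#' @return the sequence with its `feedback_valid` column filled in.
#' @export
schedule_feedback_reversal <- function(seq, rate = NULL, seed = 1L) {
  config <- attr(seq, "config")
  rate <- rate %||% config$reversal_rate
  if (!rate %in% c(0, 0.05, 0.10, 0.20))
    stop("`rate` must be one of 0, 0.05, 0.10, 0.20", call. = FALSE)
  seq$feedback_valid <- TRUE
  n_rev <- as.integer(floor(rate * nrow(seq) + 0.5))
  if (n_rev == 0L) return(seq)
  with_seed(seed, {
    sounds <- sample(unique(seq$audio_tactile))
    quota <- rep(seq_along(sounds), length.out = n_rev)
    flagged <- integer(0)
    for (k in seq_along(sounds)) {
      nk <- sum(quota == k)
      if (nk == 0L) next
      idx <- which(seq$audio_tactile == sounds[k])
      flagged <- c(flagged, sample(idx, nk))
    }
    seq$feedback_valid[flagged] <- FALSE
    seq
  })
}

#' Sample trial timing
#'
#' Draws per-trial inter-trial and inter-stimulus intervals from gamma
#' distributions (shape 4, scale calibrated so the truncated mean equals
#' the configured mean, truncation to the configured range by rejection)
#' and accumulates event onsets: ITI, stimulus (2 s), ISI, feedback.
#'
#' @param seq an `msl_sequence`.
#' @param seed integer seed.
#' @return the sequence with `iti`, `isi`, `onset_stimulus` and
#'   `onset_feedback` columns filled in (seconds from run start).
#' @export
sample_timing <- function(seq, seed = 1L) {
  config <- attr(seq, "config")
  n <- nrow(seq)
  with_seed(seed, {
    iti <- rtrunc_gamma(n, config$iti_mean, config$iti_range[1],
                        config$iti_range[2])
    isi <- rtrunc_gamma(n, config$isi_mean, config$isi_range[1],
                        config$isi_range[2])
    seq$iti <- iti
    seq$isi <- isi
    onset_stim <- numeric(n)
    onset_fb <- numeric(n)
    t0 <- 0
    for (i in seq_len(n)) {
      onset_stim[i] <- t0 + iti[i]
      onset_fb[i] <- onset_stim[i] + config$stimulus_duration + isi[i]
      t0 <- onset_fb[i] + config$feedback_duration
    }
    seq$onset_stimulus <- onset_stim
    seq$onset_feedback <- onset_fb
    seq
  })
}

#' Build a complete run design
#'
#' Convenience wrapper: trial sequence, feedback-reversal schedule and
#' timing in one deterministic call (sub-seeds derived from `seed`).
#'
#' @inheritParams make_trial_sequence
#' @return an `msl_sequence` with all columns populated.
#' @export
design_run <- function(config, seed) {
  ss <- child_seeds(seed, 3L)
  seq <- make_trial_sequence(config, ss[1])
  seq <- schedule_feedback_reversal(seq, seed = ss[2])
  sample_timing(seq, seed = ss[3])
}

#' Write / read a trial sequence as TSV
#'
#' @param seq an `msl_sequence`.
#' @param path file path.
#' @export
write_sequence <- function(seq, path) {
  write.table(as.data.frame(seq), path, sep = "\t", quote = FALSE,
              row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_sequence
#' @param config optionally, the [task_config()] the file was generated
#'   from; inferred from the columns when omitted.
#' @export
read_sequence <- function(path, config = NULL) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                   colClasses = NA)
  for (col in c("audio_tactile", "visual", "visual_left", "visual_right",
                "correct_side"))
    if (col %in% names(df)) df[[col]] <- as.character(df[[col]])
  variant <- if ("visual_left" %in% names(df)) "discriminative_choice"
             else "match_recognition"
  if (is.null(config)) config <- task_config(variant)
  if (config$variant != variant)
    stop("file columns do not match the supplied config", call. = FALSE)
  if (any(diff(df$onset_stimulus) <= 0, na.rm = TRUE))
    stop("onsets are not strictly increasing", call. = FALSE)
  structure(df, config = config, class = c("msl_sequence", "data.frame"))
}
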