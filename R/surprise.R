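# Trial-wise Shannon surprise from Laplace-smoothed combination frequencies.

#' Laplace-smoothed combination probability
#'
#' Probability of observing combination `current` after `history`, with `n`
#' nominal combinations: `(1 + occurrences in history) / (n + t)` where `t`
#' is the number of trials observed so far.  The first trial therefore has
#' probability `1/n` for every combination.
#'
#' @param history vector of previously observed combination keys (possibly
#'   empty).
#' @param current the combination of the current trial.
#' @param n number of nominal combinations (>= 2).
#' @return a probability in (0, 1].
#' @export
#' @examples
#' combination_probability(character(0), "A.0", 9)  # 1/9
combination_probability <- function(history, current, n) {
  if (!is.numeric(n) || length(n) != 1L || n < 2)
    stop("`n` must be a single count >= 2", call. = FALSE)
  (1 + sum(history == current)) / (n + length(history))
}

surprise_from_keys <- function(keys, n) {
  t_n <- length(keys)
  p <- numeric(t_n)
  counts <- integer(0)
  for (t in seq_len(t_n)) {
    k <- keys[t]
    c_k <- if (k %in% names(counts)) counts[[k]] else 0L
    p[t] <- (1 + c_k) / (n + (t - 1))
    counts[k] <- c_k + 1L
  }
  data.frame(trial = seq_len(t_n) - 1L, key = keys, p = p,
             surprise = -log(p), stringsAsFactors = FALSE)
}

#' Shannon surprise trace of a run
#'
#' Sequentially applies [combination_probability()] over the run and
#' returns `-log p` (natural log, nats) per trial.  The tracked event is
#' the full stimulus combination: the unordered triplet of sound and both
#' visuals in the discriminative choice task (`n = 16` as used in the
#' source design, even though only 12 distinct triplets are realisable;
#' see `n_override`), the presented pair in the match recognition task
#' (`n = 9`).
#'
#' @param seq an `msl_sequence`.
#' @param n_override replace the default number of nominal combinations,
#'   e.g. 12 for a sensitivity analysis of the triplet count.
#' @return data frame of class `msl_surprise` with columns `trial`, `key`,
#'   `p`, `surprise`; the combination count is kept in attribute `n`.
#' @export
surprise_trace <- function(seq, n_override = NULL) {
  config <- attr(seq, "config")
  if (config$variant == "discriminative_choice") {
    v1 <- pmin(seq$visual_left, seq$visual_right)
    v2 <- pmax(seq$visual_left, seq$visual_right)
    keys <- paste(seq$audio_tactile, v1, v2, sep = ".")
    n <- n_override %||% 16L
  } else {
    keys <- paste(seq$audio_tactile, seq$visual, sep = ".")
    n <- n_override %||% 9L
  }
  out <- surprise_from_keys(keys, n)
  structure(out, n = n, type = "combination",
            class = c("msl_surprise", "data.frame"))
}

#' Non-matching-pair surprise (discriminative choice only)
#'
#' In the discriminative choice task the matching symbol is shown on every
#' trial of its sound, so no surprise attaches to it; this variant tracks
#' only the (sound, non-matching visual) pair, with `n = 4` possible
#' non-matching pairs per trial.
#'
#' @inheritParams surprise_trace
#' @export
nonmatching_surprise_trace <- function(seq) {
  config <- attr(seq, "config")
  if (config$variant != "discriminative_choice")
    stop("non-matching surprise is defined only for the discriminative choice task",
         call. = FALSE)
  m <- pairing_frequency_table(config)$matching
  match_vis <- unname(m[seq$audio_tactile])
  nonmatch <- ifelse(seq$visual_left == match_vis,
                     seq$visual_right, seq$visual_left)
  keys <- paste(seq$audio_tactile, nonmatch, sep = ".")
  out <- surprise_from_keys(keys, 4L)
  structure(out, n = 4L, type = "nonmatching",
            class = c("msl_surprise", "data.frame"))
}

#' @rdname surprise_trace
#' @param trace an `msl_surprise` trace.
#' @param path file path for the TSV writer.
#' @export
write_surprise <- function(trace, path) {
  write.table(as.data.frame(trace), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
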