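# Package-level I/O and the end-to-end pipeline.

#' Write a joined per-trial run table
#'
#' One tidy TSV per run: the sequence columns joined with `response`,
#' `rt` and `feedback` - the interchange format between all pipeline
#' stages.
#'
#' @param seq an `msl_sequence`.
#' @param behaviour the aligned `msl_behaviour` record.
#' @param path file path.
#' @export
write_behaviour <- function(seq, behaviour, path) {
  stopifnot(nrow(seq) == nrow(behaviour))
  df <- cbind(as.data.frame(seq),
              behaviour[, c("response", "rt", "feedback")])
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}

#' Read a joined per-trial run table
#'
#' Header-driven (column order free); validates required columns, onset
#' monotonicity, response/feedback labels and the omission contract
#' (`rt` is `NA`, never 0, on omission rows), reporting offending row
#' numbers.
#'
#' @param path file path written by [write_behaviour()].
#' @param config optional [task_config()]; inferred when omitted.
#' @return list with `sequence` and `behaviour`.
#' @export
read_behaviour <- function(path, config = NULL) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  for (col in c("audio_tactile", "visual", "visual_left", "visual_right",
                "correct_side", "response", "feedback"))
    if (col %in% names(df)) df[[col]] <- as.character(df[[col]])
  variant <- if ("visual_left" %in% names(df)) "discriminative_choice"
             else "match_recognition"
  need <- c("trial", "audio_tactile", "feedback_valid", "onset_stimulus",
            "onset_feedback", "response", "rt", "feedback",
            if (variant == "discriminative_choice")
              c("visual_left", "visual_right", "correct_side")
            else c("visual", "is_match"))
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  df <- df[order(df$trial), ]
  if (any(diff(df$onset_stimulus) <= 0))
    stop("onsets are not strictly increasing", call. = FALSE)
  if (is.null(config)) config <- task_config(variant)
  labs_at <- at_labels(config$n_audio_tactile)
  bad <- which(!df$audio_tactile %in% labs_at)
  if (length(bad))
    stop("unknown audio/tactile stimulus id at row(s): ",
         paste(head(bad, 5), collapse = ", "), call. = FALSE)
  ok_resp <- if (variant == "discriminative_choice") c("left", "right")
             else c("match", "nonmatch")
  bad <- which(!is.na(df$response) & !df$response %in% ok_resp)
  if (length(bad))
    stop("unknown response label at row(s): ",
         paste(head(bad, 5), collapse = ", "), call. = FALSE)
  bad <- which(is.na(df$response) & !is.na(df$rt))
  if (length(bad))
    stop("omission rows must have missing rt, offending row(s): ",
         paste(head(bad, 5), collapse = ", "), call. = FALSE)
  seq_cols <- setdiff(names(df), c("response", "rt", "feedback"))
  seq <- structure(df[, seq_cols], config = config,
                   class = c("msl_sequence", "data.frame"))
  beh <- structure(df[, c("trial", "response", "rt", "feedback")],
                   config = config,
                   class = c("msl_behaviour", "data.frame"))
  list(sequence = seq, behaviour = beh)
}

read_pipeline_config <- function(config) {
  if (is.character(config)) {
    config <- if (grepl("\\.ya?ml$", config)) yaml::read_yaml(config)
              else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  stopifnot(is.list(config))
  config
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' design -> simulate -> surprise -> fit -> select -> analyse -> export,
#' with one output directory per run and a reproducibility manifest
#' recording every seed.  The configuration is a list (or a YAML/JSON file
#' path) with fields `variant`, `group`, `n_subjects` and optionally
#' `model` (generating variant), `reversal_rate`, `models` (variants to
#' fit), `n_restarts`, `modalities`, `dt`.
#'
#' @param config list or path to a YAML/JSON configuration file.
#' @param seed integer master seed.
#' @param out_dir output directory.
#' @return invisibly, the manifest list (also written as
#'   `manifest.json`).
#' @export
run_pipeline <- function(config, seed, out_dir) {
  cfg <- read_pipeline_config(config)
  stopifnot(!is.null(cfg$variant), !is.null(cfg$n_subjects))
  models <- cfg[["models"]] %||% MSL_MODELS
  n_restarts <- cfg[["n_restarts"]] %||% 8L
  dt <- cfg[["dt"]] %||% 1e-3
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

  spec <- cohort_spec(cfg$n_subjects, cfg$variant,
                      group = cfg[["group"]] %||% "child",
                      model = cfg[["model"]] %||% "simple",
                      reversal_rate = cfg[["reversal_rate"]] %||% 0.1,
                      modalities = cfg[["modalities"]] %||%
                        c("audio_visual", "tactile_visual"))
  seeds <- child_seeds(seed, 2L)
  cohort <- simulate_cohort(spec, seed = seeds[1], dt = dt)
  fit_seeds <- child_seeds(seeds[2], length(cohort$runs))

  manifest <- list(seed = seed, config = cfg, runs = list())
  fit_rows <- list()
  for (k in seq_along(cohort$runs)) {
    run <- cohort$runs[[k]]
    run_id <- sprintf("sub%02d_%s", run$subject,
                      ifelse(run$modality == "audio_visual", "av", "tv"))
    rd <- file.path(out_dir, run_id)
    if (!dir.exists(rd)) dir.create(rd)
    stage <- "io"
    res <- tryCatch({
      write_behaviour(run$seq, run$behaviour, file.path(rd, "run.tsv"))
      stage <- "surprise"
      sur <- surprise_trace(run$seq)
      write_surprise(sur, file.path(rd, "surprise.tsv"))
      stage <- "fit"
      fm <- fit_models(run$seq, run$behaviour, models = models,
                       n_restarts = n_restarts, seed = fit_seeds[k])
      best <- fm$fits[[fm$best]]
      jsonlite::write_json(
        list(model = best$model, params = as.list(best$params),
             logL = best$logL, BIC = best$BIC,
             n_trials_used = best$n_trials_used,
             bic_all = as.list(fm$bic)),
        file.path(rd, "fit.json"), auto_unbox = TRUE, digits = NA)
      stage <- "traces"
      traces <- run_model(run$seq, run$behaviour, best$rl, best$ddm)
      write_traces(traces, file.path(rd, "traces.tsv"))
      stage <- "analyze"
      fl <- filter_trials(run$behaviour)
      write.table(fl$log, file.path(rd, "exclusions.csv"), sep = ",",
                  quote = FALSE, row.names = FALSE)
      bins <- bin_summaries(run$seq, run$behaviour, traces, fl)
      write.table(bins, file.path(rd, "bins.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE, na = "NA")
      stage <- "export"
      export_regressors(run$seq, run$behaviour, traces, sur, fl, dir = rd)
      list(best = fm$best, bic = fm$bic, fl = fl, params = best$params)
    }, error = function(e)
      stop("pipeline stage '", stage, "' failed for run ", run_id, ": ",
           conditionMessage(e), call. = FALSE))
    fit_rows[[k]] <- data.frame(run = run_id, subject = run$subject,
                                modality = run$modality, model = res$best,
                                t(res$params), run_excluded = res$fl$run_excluded)
    manifest$runs[[run_id]] <- list(
      dir = run_id, subject = run$subject, modality = run$modality,
      fit_seed = fit_seeds[k], selected_model = res$best,
      run_excluded = res$fl$run_excluded)
  }
  fits <- do.call(rbind, lapply(fit_rows, function(d) {
    base <- d[, c("run", "subject", "modality", "model", "run_excluded")]
    pars <- d[, setdiff(names(d), names(base)), drop = FALSE]
    cbind(base, pars)
  }))
  write.table(fits, file.path(out_dir, "fits.csv"), sep = ",",
              quote = FALSE, row.names = FALSE, na = "NA")
  jsonlite::write_json(cohort$truth, file.path(out_dir, "truth.json"),
                       digits = NA)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
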