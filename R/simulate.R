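# Forward simulation of behavioural runs and cohorts from the generative
# reinforcement-learning diffusion model.

# population parameter anchors: printed per-group/modality means (SDs) of
# the fitted learning rate, non-decision time, drift weight and boundary
.param_anchors <- data.frame(
  variant  = rep(c("match_recognition", "discriminative_choice"), c(4, 2)),
  group    = c("adult", "adult", "child", "child", "child", "child"),
  modality = rep(c("audio_visual", "tactile_visual"), 3),
  eta_mean = c(0.35, 0.23, 0.38, 0.38, 0.33, 0.36),
  eta_sd   = c(0.28, 0.25, 0.33, 0.36, 0.34, 0.40),
  tau_mean = c(0.69, 0.92, 0.89, 1.12, 0.90, 1.14),
  tau_sd   = c(0.20, 0.45, 0.44, 0.45, 0.30, 0.37),
  vmod_mean = c(3.60, 4.21, 1.96, 1.10, 2.42, 2.29),
  vmod_sd   = c(3.30, 3.50, 2.26, 0.93, 3.27, 3.47),
  a_mean = c(2.32, 2.28, 2.48, 2.46, 2.48, 2.59),
  a_sd   = c(0.41, 0.42, 0.42, 0.38, 0.26, 0.58),
  stringsAsFactors = FALSE
)

# admissible ranges the sampled parameters are truncated to
.param_ranges <- list(eta = c(0.01, 1), tau = c(0.1, 2),
                      vmod = c(0.05, 20), a = c(0.3, 5))

param_anchor <- function(variant, group, modality) {
  i <- which(.param_anchors$variant == variant &
             .param_anchors$group == group &
             .param_anchors$modality == modality)
  if (length(i) != 1L)
    stop("no parameter anchor for ", variant, "/", group, "/", modality,
         call. = FALSE)
  as.list(.param_anchors[i, -(1:3)])
}

#' Simulate one behavioural run
#'
#' Forward-generates choices and reaction times: per trial the drift rate
#' follows from the current association values, a response and decision
#' time are drawn from the diffusion first-passage process, feedback is
#' delivered according to correctness and the trial's scheduled feedback
#' validity (neutral for omissions beyond the response window), and the
#' value table is updated under the chosen learning variant before the
#' next trial.
#'
#' @param seq an `msl_sequence` (with timing for per-trial response
#'   windows; otherwise the configured mean ISI is used).
#' @param rl an [rl_params()] object.
#' @param ddm an [ddm_params()] object.
#' @param response_window response deadline in seconds; default is the
#'   stimulus duration plus the trial's inter-stimulus interval (responses
#'   are possible until feedback onset).
#' @param dt Euler step of the first-passage sampler.
#' @param seed integer seed.
#' @return an `msl_behaviour` data frame: `trial`, `response`, `rt`,
#'   `feedback`.
#' @export
simulate_run <- function(seq, rl, ddm, response_window = NULL, dt = 1e-3,
                         seed = 1L) {
  config <- attr(seq, "config")
  sa <- seq_arrays(seq)
  window <- response_window %||%
    (config$stimulus_duration + (seq$isi %||% rep(config$isi_mean, nrow(seq))))
  if (length(window) == 1L) window <- rep(window, nrow(seq))
  out <- simulate_cpp(sa$task, model_code(rl$model), sa$n_at, sa$n_vis,
                      sa$at, sa$vm, sa$vo, sa$side, sa$is_match,
                      as.integer(seq$feedback_valid), window,
                      eta_vector(rl), ddm$vmod, ddm$a, ddm$tau, dt, seed)
  resp <- rep(NA_character_, nrow(seq))
  if (sa$task == 0L) {
    resp[out$response == 0L] <- "left"
    resp[out$response == 1L] <- "right"
  } else {
    resp[out$response == 1L] <- "match"
    resp[out$response == 0L] <- "nonmatch"
  }
  fb <- ifelse(out$feedback == 1L, "positive",
               ifelse(out$feedback == 0L, "negative", "neutral"))
  structure(data.frame(trial = seq$trial, response = resp, rt = out$rt,
                       feedback = fb, stringsAsFactors = FALSE),
            config = config, class = c("msl_behaviour", "data.frame"))
}

#' Cohort specification for synthetic data
#'
#' Population distributions of the generative parameters are truncated
#' normals anchored on the printed per-group parameter means and SDs;
#' each subject completes one audio-visual and one tactile-visual run.
#'
#' @param n_subjects number of subjects.
#' @param variant,group task variant and age group (select the anchors).
#' @param model generating learning variant.
#' @param reversal_rate feedback reversal rate for every run.
#' @param modalities which runs each subject completes.
#' @param overrides optional named list replacing individual anchor values,
#'   e.g. `list(audio_visual = list(vmod_mean = 3))`.
#' @return class `msl_cohort_spec`.
#' @export
cohort_spec <- function(n_subjects,
                        variant = c("match_recognition", "discriminative_choice"),
                        group = c("child", "adult"),
                        model = "simple",
                        reversal_rate = 0.1,
                        modalities = c("audio_visual", "tactile_visual"),
                        overrides = NULL) {
  variant <- match.arg(variant)
  group <- match.arg(group)
  stopifnot(n_subjects >= 1, model %in% MSL_MODELS)
  pop <- lapply(modalities, function(mod) {
    an <- param_anchor(variant, group, mod)
    if (!is.null(overrides[[mod]])) an[names(overrides[[mod]])] <- overrides[[mod]]
    an
  })
  names(pop) <- modalities
  structure(list(n_subjects = as.integer(n_subjects), variant = variant,
                 group = group, model = model,
                 reversal_rate = reversal_rate, modalities = modalities,
                 population = pop),
            class = "msl_cohort_spec")
}

draw_params <- function(anchor, model) {
  dr <- function(nm, rng) rtruncnorm(1, anchor[[paste0(nm, "_mean")]],
                                     anchor[[paste0(nm, "_sd")]],
                                     rng[1], rng[2])
  eta <- dr("eta", .param_ranges$eta)
  rl <- switch(model,
    simple = rl_params("simple", eta_c = eta),
    simple_asym = rl_params("simple_asym", eta_c_pos = eta,
                            eta_c_neg = dr("eta", .param_ranges$eta)),
    transfer = rl_params("transfer", eta_c = eta,
                         eta_o = dr("eta", .param_ranges$eta)),
    transfer_asym = rl_params("transfer_asym",
                              eta_c_pos = eta,
                              eta_c_neg = dr("eta", .param_ranges$eta),
                              eta_o = dr("eta", .param_ranges$eta)))
  ddm <- ddm_params(vmod = dr("vmod", .param_ranges$vmod),
                    a = dr("a", .param_ranges$a),
                    tau = dr("tau", .param_ranges$tau))
  list(rl = rl, ddm = ddm)
}

#' Simulate a cohort of behavioural runs
#'
#' Per subject and modality, draws generative parameters from the
#' population distributions, designs a fresh run and simulates behaviour.
#'
#' @param spec a [cohort_spec()].
#' @param seed integer seed; the full dataset is reproducible from it.
#' @param dt Euler step passed to [simulate_run()].
#' @return class `msl_cohort`: list with `runs` (each holding `subject`,
#'   `modality`, `seq`, `behaviour`, `rl`, `ddm`), `truth` (ground-truth
#'   parameter table, one row per run) and `trials` (tidy per-trial table
#'   across all runs).
#' @export
simulate_cohort <- function(spec, seed = 1L, dt = 1e-3) {
  stopifnot(inherits(spec, "msl_cohort_spec"))
  n_runs <- spec$n_subjects * length(spec$modalities)
  seeds <- child_seeds(seed, 3L * n_runs + 1L)
  par_seed <- seeds[length(seeds)]
  runs <- vector("list", n_runs)
  truth <- vector("list", n_runs)
  k <- 0L
  for (subj in seq_len(spec$n_subjects)) {
    for (mod in spec$modalities) {
      k <- k + 1L
      config <- task_config(spec$variant, modality = mod, group = spec$group,
                            reversal_rate = spec$reversal_rate)
      pars <- with_seed(par_seed + k, draw_params(spec$population[[mod]],
                                                  spec$model))
      seq <- design_run(config, seeds[3L * k - 2L])
      beh <- simulate_run(seq, pars$rl, pars$ddm, dt = dt,
                          seed = seeds[3L * k - 1L])
      runs[[k]] <- list(subject = subj, modality = mod, seq = seq,
                        behaviour = beh, rl = pars$rl, ddm = pars$ddm)
      eta4 <- eta_vector(pars$rl)
      truth[[k]] <- data.frame(subject = subj, modality = mod,
                               model = spec$model,
                               eta_c_pos = eta4[1], eta_c_neg = eta4[2],
                               eta_o_pos = eta4[3], eta_o_neg = eta4[4],
                               vmod = pars$ddm$vmod, a = pars$ddm$a,
                               tau = pars$ddm$tau,
                               stringsAsFactors = FALSE)
    }
  }
  trials <- do.call(rbind, lapply(runs, function(r)
    cbind(subject = r$subject, modality = r$modality,
          as.data.frame(r$seq), r$behaviour[, c("response", "rt", "feedback")])))
  structure(list(spec = spec, runs = runs, truth = do.call(rbind, truth),
                 trials = trials, seed = seed),
            class = "msl_cohort")
}

#' @export
print.msl_cohort <- function(x, ...) {
  cat("<msl_cohort>", x$spec$n_subjects, "subjects x",
      length(x$spec$modalities), "runs,", x$spec$variant, "/",
      x$spec$group, "\n")
  invisible(x)
}
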