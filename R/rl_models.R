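# Rescorla-Wagner learning variants and the value-to-drift mapping.

MSL_MODELS <- c("simple", "simple_asym", "transfer", "transfer_asym")

task_code <- function(config) {
  if (config$variant == "discriminative_choice") 0L else 1L
}
model_code <- function(model) match(model, MSL_MODELS) - 1L

#' Learning-rule parameters
#'
#' The four Rescorla-Wagner variants: `simple` updates only the chosen
#' (discriminative choice) or presented (match recognition) pair;
#' `simple_asym` uses separate learning rates after positive and negative
#' feedback; `transfer` additionally updates the other presented pair
#' toward the complement of the outcome (discriminative choice) or moves
#' all pairs sharing a unisensory stimulus with the presented pair toward
#' zero after positive feedback (match recognition); `transfer_asym`
#' combines both.  All rates live in \[0, 1\].
#'
#' @param model variant name.
#' @param eta_c learning rate of the chosen/presented pair (symmetric
#'   variants).
#' @param eta_c_pos,eta_c_neg rates after positive/negative feedback
#'   (asymmetric variants).
#' @param eta_o transfer rate for the other/overlapping pairs.
#' @param eta_o_pos,eta_o_neg feedback-sign-specific transfer rates
#'   (asymmetric transfer, discriminative choice only; match recognition
#'   transfer fires only after positive feedback and keeps a single
#'   `eta_o`).
#' @return class `msl_rl_params`.
#' @export
rl_params <- function(model = MSL_MODELS, eta_c = NULL,
                      eta_c_pos = NULL, eta_c_neg = NULL, eta_o = NULL,
                      eta_o_pos = NULL, eta_o_neg = NULL) {
  model <- match.arg(model)
  chk <- function(x, nm) {
    if (is.null(x)) stop("`", nm, "` is required for model '", model, "'",
                         call. = FALSE)
    if (x < 0 || x > 1) stop("`", nm, "` must be in [0, 1]", call. = FALSE)
    x
  }
  p <- list(model = model)
  if (model %in% c("simple", "transfer")) {
    p$eta_c <- chk(eta_c, "eta_c")
  } else {
    p$eta_c_pos <- chk(eta_c_pos, "eta_c_pos")
    p$eta_c_neg <- chk(eta_c_neg, "eta_c_neg")
  }
  if (model == "transfer") p$eta_o <- chk(eta_o, "eta_o")
  if (model == "transfer_asym") {
    if (!is.null(eta_o_pos) || !is.null(eta_o_neg)) {
      p$eta_o_pos <- chk(eta_o_pos, "eta_o_pos")
      p$eta_o_neg <- chk(eta_o_neg, "eta_o_neg")
    } else {
      p$eta_o <- chk(eta_o, "eta_o")
    }
  }
  structure(p, class = "msl_rl_params")
}

# expand to the uniform (eta_c_pos, eta_c_neg, eta_o_pos, eta_o_neg) vector
# consumed by the compiled forward pass
eta_vector <- function(params) {
  p <- params
  ec <- if (!is.null(p$eta_c)) c(p$eta_c, p$eta_c)
        else c(p$eta_c_pos, p$eta_c_neg)
  eo <- if (!is.null(p$eta_o)) c(p$eta_o, p$eta_o)
        else if (!is.null(p$eta_o_pos)) c(p$eta_o_pos, p$eta_o_neg)
        else c(0, 0)
  c(ec, eo)
}

#' Diffusion-model parameters
#'
#' @param vmod drift weight: scaling from value difference to drift rate,
#'   interpretable as behavioural sensitivity to value differences.
#' @param a boundary separation (> 0, evidence units).
#' @param tau non-decision time in seconds (>= 0).
#' @param z relative starting point; fixed at 0.5 (no initial bias) and
#'   never a free parameter.
#' @return class `msl_ddm_params`.
#' @export
ddm_params <- function(vmod, a, tau, z = 0.5) {
  stopifnot(a > 0, tau >= 0, z > 0, z < 1, vmod >= 0)
  if (z != 0.5)
    warning("the starting point is fixed at 0.5 in the fitted model")
  structure(list(vmod = vmod, a = a, tau = tau, z = z),
            class = "msl_ddm_params")
}

#' Reward prediction error
#'
#' `R - V`: delivered binary feedback minus the current association value.
#'
#' @param R binary outcome (1 positive, 0 negative).
#' @param V value in \[0, 1\].
#' @export
reward_prediction_error <- function(R, V) {
  stopifnot(all(R %in% c(0, 1)), all(V >= 0 & V <= 1))
  R - V
}

#' Odds-ratio value normalisation
#'
#' Maps the two competing pair values onto complementary weights
#' `Vc(1-Vo) / (Vc(1-Vo) + Vo(1-Vc))`, clamping both inputs to
#' `[eps, 1-eps]` so the ratio stays defined at the extremes.
#'
#' @param v_c,v_o values of the chosen and other pair.
#' @param eps clamping margin.
#' @return list with `c` and `o` components summing to 1.
#' @export
normalize_values <- function(v_c, v_o, eps = 1e-6) {
  c_ <- pmin(pmax(v_c, eps), 1 - eps)
  o_ <- pmin(pmax(v_o, eps), 1 - eps)
  num <- c_ * (1 - o_)
  nc <- num / (num + o_ * (1 - c_))
  list(c = nc, o = 1 - nc)
}

#' Trial drift rate from association values
#'
#' Discriminative choice: the difference between the normalised values of
#' the two presented pairs times the drift weight.  Match recognition: the
#' presented pair's value against its complement, `(2V - 1) * vmod`.
#'
#' @param v_c value of the chosen/first (or presented) pair.
#' @param v_o value of the other pair (discriminative choice only).
#' @param vmod drift weight.
#' @param variant task variant.
#' @export
drift_rate <- function(v_c, v_o = NULL, vmod,
                       variant = c("discriminative_choice", "match_recognition")) {
  variant <- match.arg(variant)
  if (variant == "discriminative_choice") {
    if (is.null(v_o)) stop("`v_o` is required for the discriminative choice task")
    nv <- normalize_values(v_c, v_o)
    (nv$c - nv$o) * vmod
  } else {
    (2 * v_c - 1) * vmod
  }
}

# encode sequence + behaviour into the integer arrays the compiled code uses
seq_arrays <- function(seq) {
  config <- attr(seq, "config")
  at <- match(seq$audio_tactile, at_labels(config$n_audio_tactile)) - 1L
  if (config$variant == "discriminative_choice") {
    m <- pairing_frequency_table(config)$matching
    match_vis <- unname(m[seq$audio_tactile])
    nonmatch <- ifelse(seq$visual_left == match_vis,
                       seq$visual_right, seq$visual_left)
    list(task = 0L,
         n_at = config$n_audio_tactile, n_vis = config$n_visual,
         at = at,
         vm = match(match_vis, vis_labels(config$n_visual)) - 1L,
         vo = match(nonmatch, vis_labels(config$n_visual)) - 1L,
         side = ifelse(seq$correct_side == "left", 0L, 1L),
         is_match = rep(-1L, nrow(seq)))
  } else {
    list(task = 1L,
         n_at = config$n_audio_tactile, n_vis = config$n_visual,
         at = at,
         vm = match(seq$visual, vis_labels(config$n_visual)) - 1L,
         vo = rep(-1L, nrow(seq)),
         side = rep(-1L, nrow(seq)),
         is_match = as.integer(seq$is_match))
  }
}

behaviour_arrays <- function(behaviour, task) {
  resp <- behaviour$response
  r <- rep(-1L, length(resp))
  if (task == 0L) {
    r[!is.na(resp) & resp == "left"] <- 0L
    r[!is.na(resp) & resp == "right"] <- 1L
  } else {
    r[!is.na(resp) & resp == "match"] <- 1L
    r[!is.na(resp) & resp == "nonmatch"] <- 0L
  }
  fb <- rep(-1L, length(resp))
  fb[behaviour$feedback == "positive"] <- 1L
  fb[behaviour$feedback == "negative"] <- 0L
  list(resp = r, fb = fb, rt = as.numeric(behaviour$rt))
}

#' Forward pass of the learning model over one run
#'
#' Deterministically replays the run: per trial the drift rate is computed
#' from the current value table (in the fixed left-minus-right or
#' match-minus-nonmatch frame), then the value table is updated with the
#' delivered feedback under the chosen learning variant.  Omitted trials
#' (neutral feedback) leave the values untouched.
#'
#' @param seq an `msl_sequence`.
#' @param behaviour a behavioural record aligned with `seq` (columns
#'   `response`, `rt`, `feedback`).
#' @param params an [rl_params()] object.
#' @param vmod drift weight (or an [ddm_params()] object).
#' @return data frame with per-trial `V_chosen`, `V_other`, `RPE`, `drift`.
#' @export
run_model <- function(seq, behaviour, params, vmod) {
  if (inherits(vmod, "msl_ddm_params")) vmod <- vmod$vmod
  if (nrow(seq) != nrow(behaviour))
    stop("sequence and behaviour have different lengths", call. = FALSE)
  sa <- seq_arrays(seq)
  ba <- behaviour_arrays(behaviour, sa$task)
  out <- forward_cpp(sa$task, model_code(params$model), sa$n_at, sa$n_vis,
                     sa$at, sa$vm, sa$vo, sa$side, ba$resp, ba$fb,
                     eta_vector(params), vmod)
  data.frame(trial = seq$trial, V_chosen = out$v_chosen,
             V_other = out$v_other, RPE = out$rpe, drift = out$drift)
}

#' @rdname run_model
#' @param traces a trace data frame from `run_model()`.
#' @param path file path for the TSV writer.
#' @export
write_traces <- function(traces, path) {
  write.table(traces, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}
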