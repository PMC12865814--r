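# Per-run maximum-likelihood estimation, BIC model selection and
# parameter/model recovery harnesses.

# free-parameter layout per (task, model); DDM parameters are always the
# trailing (vmod, a, tau); the starting point z = 0.5 and the initial
# values V0 = 0.5 are fixed, never fitted
param_names <- function(task, model) {
  eta <- switch(model,
    simple = "eta_c",
    simple_asym = c("eta_c_pos", "eta_c_neg"),
    transfer = c("eta_c", "eta_o"),
    transfer_asym = if (task == 0L)
      c("eta_c_pos", "eta_c_neg", "eta_o_pos", "eta_o_neg")
    else c("eta_c_pos", "eta_c_neg", "eta_o"))
  c(eta, "vmod", "a", "tau")
}

unpack_params <- function(theta, task, model) {
  nm <- param_names(task, model)
  th <- setNames(as.numeric(theta), nm)
  rl <- switch(model,
    simple = rl_params("simple", eta_c = th["eta_c"]),
    simple_asym = rl_params("simple_asym", eta_c_pos = th["eta_c_pos"],
                            eta_c_neg = th["eta_c_neg"]),
    transfer = rl_params("transfer", eta_c = th["eta_c"],
                         eta_o = th["eta_o"]),
    transfer_asym = if (task == 0L)
      rl_params("transfer_asym", eta_c_pos = th["eta_c_pos"],
                eta_c_neg = th["eta_c_neg"], eta_o_pos = th["eta_o_pos"],
                eta_o_neg = th["eta_o_neg"])
    else rl_params("transfer_asym", eta_c_pos = th["eta_c_pos"],
                   eta_c_neg = th["eta_c_neg"], eta_o = th["eta_o"]))
  list(rl = rl, ddm = ddm_params(th["vmod"], th["a"], th["tau"]))
}

#' Default box constraints for fitting
#'
#' Learning rates in \[0, 1\], drift weight in \[0, 20\], boundary in
#' \[0.3, 5\] and non-decision time in \[0.1, min observed RT - 0.01 s\].
#'
#' @param behaviour the run's behavioural record (for the RT bound).
#' @param task,model internal codes / variant name.
#' @return list with `lower` and `upper` named vectors.
#' @export
default_bounds <- function(behaviour, task = 1L, model = "simple") {
  nm <- param_names(task, model)
  min_rt <- suppressWarnings(min(behaviour$rt, na.rm = TRUE))
  tau_hi <- if (is.finite(min_rt)) max(0.12, min_rt - 0.01) else 1.5
  lower <- setNames(rep(0, length(nm)), nm)
  upper <- setNames(rep(1, length(nm)), nm)
  lower["vmod"] <- 0; upper["vmod"] <- 20
  lower["a"] <- 0.3; upper["a"] <- 5
  lower["tau"] <- 0.1; upper["tau"] <- tau_hi
  list(lower = lower, upper = upper)
}

# trials entering the likelihood: responses present, not excluded by the
# RT filters; values still evolve over every feedback trial
default_include <- function(seq, behaviour) {
  fl <- filter_trials(behaviour)
  behaviour$trial %in% fl$data$trial
}

#' Negative log-likelihood of a run under the learning-diffusion model
#'
#' Sum over included response trials of the negative log first-passage
#' likelihood, with trial-wise drift rates from the forward pass of the
#' learning rule (values evolve over all feedback trials, including those
#' excluded from the likelihood).
#'
#' @param seq,behaviour the run.
#' @param rl,ddm parameter objects.
#' @param include logical vector flagging likelihood trials; defaults to
#'   the trials surviving [filter_trials()].
#' @return the negative log-likelihood in nats (`+Inf` for invalid
#'   parameters).
#' @export
negative_log_likelihood <- function(seq, behaviour, rl, ddm,
                                    include = NULL) {
  sa <- seq_arrays(seq)
  ba <- behaviour_arrays(behaviour, sa$task)
  include <- include %||% default_include(seq, behaviour)
  rt <- ba$rt
  rt[is.na(rt)] <- -1
  nll_cpp(sa$task, model_code(rl$model), sa$n_at, sa$n_vis, sa$at, sa$vm,
          sa$vo, sa$side, ba$resp, ba$fb, include, rt,
          eta_vector(rl), ddm$vmod, ddm$a, ddm$tau)
}

#' Bayesian information criterion
#'
#' `k ln(N) - 2 logL` with `k` free parameters and `N` likelihood trials.
#'
#' @param logL log-likelihood (nats).
#' @param n_params number of free parameters.
#' @param n_trials number of trials in the likelihood (>= 1).
#' @export
bic <- function(logL, n_params, n_trials) {
  stopifnot(n_trials >= 1)
  n_params * log(n_trials) - 2 * logL
}

#' Fit one run by seeded multi-start maximum likelihood
#'
#' Minimises the negative log-likelihood over the bounded parameter box
#' with `n_restarts` quasi-Newton starts (one anchored at a plausible
#' interior point, the rest drawn uniformly in the box under `seed`).
#'
#' @param seq,behaviour the run.
#' @param model learning variant to fit.
#' @param n_restarts number of optimiser starts (>= 1).
#' @param seed integer seed controlling the starts.
#' @param include likelihood trial mask, see [negative_log_likelihood()].
#' @param bounds optional list with `lower`/`upper` named vectors.
#' @return class `msl_fit`: fitted parameters, `logL`, `BIC`, counts and
#'   optimiser diagnostics.  Non-convergence of every restart is flagged
#'   in `$converged`, not raised as an error.
#' @export
fit_run <- function(seq, behaviour, model = "simple", n_restarts = 8L,
                    seed = 1L, include = NULL, bounds = NULL) {
  stopifnot(model %in% MSL_MODELS)
  sa <- seq_arrays(seq)
  ba <- behaviour_arrays(behaviour, sa$task)
  include <- include %||% default_include(seq, behaviour)
  omission_rate <- mean(ba$resp < 0L)
  if (omission_rate > 0.2)
    warning("run has more than 20% omissions; it would be excluded from analysis")
  bounds <- bounds %||% default_bounds(behaviour, sa$task, model)
  lower <- bounds$lower
  upper <- bounds$upper
  nm <- param_names(sa$task, model)
  rt <- ba$rt
  rt[is.na(rt)] <- -1
  etas4 <- function(th) eta_vector(unpack_params(th, sa$task, model)$rl)
  obj <- function(th) {
    names(th) <- nm
    val <- nll_cpp(sa$task, model_code(model), sa$n_at, sa$n_vis, sa$at,
                   sa$vm, sa$vo, sa$side, ba$resp, ba$fb, include, rt,
                   etas4(th), th["vmod"], th["a"], th["tau"])
    if (!is.finite(val)) 1e10 else val
  }
  k <- length(nm)
  starts <- with_seed(seed, {
    s <- matrix(runif(n_restarts * k), n_restarts, k)
    s <- sweep(sweep(s, 2, upper - lower, "*"), 2, lower, "+")
    # anchor the first start at a plausible interior point
    anchor <- setNames(rep(0.3, k), nm)
    anchor["vmod"] <- 2; anchor["a"] <- 2.3
    anchor["tau"] <- min(0.3, (lower["tau"] + upper["tau"]) / 2)
    s[1, ] <- pmin(pmax(anchor, lower + 1e-4), upper - 1e-4)
    s
  })
  best <- NULL
  diag_rows <- vector("list", n_restarts)
  for (i in seq_len(n_restarts)) {
    res <- tryCatch(
      nlminb(starts[i, ], obj, lower = lower, upper = upper,
             control = list(eval.max = 800, iter.max = 400)),
      error = function(e) list(objective = Inf, par = starts[i, ],
                               convergence = 1L))
    diag_rows[[i]] <- data.frame(restart = i, objective = res$objective,
                                 converged = res$convergence == 0L)
    if (is.null(best) || res$objective < best$objective) best <- res
  }
  n_used <- sum(include & ba$resp >= 0L)
  pars <- setNames(as.numeric(best$par), nm)
  logL <- -best$objective
  structure(list(
    model = model,
    params = pars,
    rl = unpack_params(pars, sa$task, model)$rl,
    ddm = ddm_params(pars["vmod"], pars["a"], pars["tau"]),
    logL = logL,
    n_params = k,
    n_trials_used = n_used,
    BIC = bic(logL, k, n_used),
    converged = any(vapply(diag_rows, function(d) d$converged, logical(1))),
    diagnostics = do.call(rbind, diag_rows),
    seed = seed
  ), class = "msl_fit")
}

#' @export
print.msl_fit <- function(x, ...) {
  cat("<msl_fit>", x$model, " logL =", round(x$logL, 2),
      " BIC =", round(x$BIC, 2), " N =", x$n_trials_used, "\n")
  print(round(x$params, 4))
  invisible(x)
}

#' Fit all learning variants and select by BIC
#'
#' @inheritParams fit_run
#' @param models variants to fit (all four by default).
#' @return list with `fits` (one `msl_fit` per variant), `best` (the
#'   selected variant name) and `bic` (named BIC vector).  Ties are broken
#'   toward the model with fewer parameters.
#' @export
fit_models <- function(seq, behaviour, models = MSL_MODELS, n_restarts = 8L,
                       seed = 1L, include = NULL) {
  include <- include %||% default_include(seq, behaviour)
  seeds <- child_seeds(seed, length(models))
  fits <- lapply(seq_along(models), function(i)
    fit_run(seq, behaviour, models[i], n_restarts, seeds[i], include))
  names(fits) <- models
  list(fits = fits, best = select_model(fits),
       bic = vapply(fits, function(f) f$BIC, numeric(1)))
}

#' Select the best-fitting variant by BIC
#'
#' @param fits a named list of `msl_fit` objects for the same run.
#' @return the selected model name (ties go to the simpler model).
#' @export
select_model <- function(fits) {
  bics <- vapply(fits, function(f) f$BIC, numeric(1))
  ks <- vapply(fits, function(f) f$n_params, numeric(1))
  ord <- order(bics, ks)
  names(fits)[ord[1]]
}

#' Aggregate per-run model selections into a count table
#'
#' @param selected character vector of selected model names.
#' @param modality parallel vector of run modalities.
#' @return a models x modality count table.
#' @export
model_count_table <- function(selected, modality) {
  table(factor(selected, levels = MSL_MODELS), modality)
}

#' Concatenate run designs into one long run
#'
#' Used by the recovery harnesses to scale the trial count (e.g. ten
#' 42-trial sequences giving one 420-trial fit); values keep evolving
#' across the joins.
#'
#' @param seqs list of `msl_sequence` objects sharing a configuration.
#' @export
concat_sequences <- function(seqs) {
  out <- do.call(rbind, lapply(seqs, as.data.frame))
  out$trial <- seq_len(nrow(out)) - 1L
  structure(out, config = attr(seqs[[1]], "config"),
            class = c("msl_sequence", "data.frame"))
}

#' Parameter recovery simulation
#'
#' Simulates runs at known parameters, refits them, and summarises the
#' agreement: correlation, bias and RMSE per parameter.  Optionally fits
#' all variants per replicate to build a model-confusion row.
#'
#' @param config a [task_config()].
#' @param true_params data frame with one row per replicate and columns
#'   `eta_c`, `vmod`, `a`, `tau` (the generating simple-variant
#'   parameters).
#' @param n_concat number of concatenated sequences per simulated run
#'   (1 = a single 42/44-trial run).
#' @param model generating and fitted variant.
#' @param n_restarts,seed optimiser settings.
#' @param fit_all_models also fit the other variants and record which wins
#'   the BIC comparison.
#' @param dt simulation Euler step.
#' @return class `msl_recovery`: `estimates` (true and recovered values
#'   per replicate), `summary` (per-parameter correlation/bias/RMSE) and,
#'   if requested, `selection` (BIC-selected variant per replicate).
#' @export
parameter_recovery <- function(config, true_params, n_concat = 1L,
                               model = "simple", n_restarts = 5L, seed = 1L,
                               fit_all_models = FALSE, dt = 1e-3) {
  n_rep <- nrow(true_params)
  seeds <- child_seeds(seed, 3L * n_rep)
  rows <- vector("list", n_rep)
  sel <- character(n_rep)
  for (r in seq_len(n_rep)) {
    tp <- true_params[r, ]
    rl <- rl_params(model, eta_c = tp$eta_c)
    ddm <- ddm_params(tp$vmod, tp$a, tp$tau)
    seqs <- lapply(seq_len(n_concat), function(j)
      design_run(config, seeds[3L * r - 2L] %% 2000000000L + j))
    long_seq <- concat_sequences(seqs)
    beh <- simulate_run(long_seq, rl, ddm, dt = dt, seed = seeds[3L * r - 1L])
    if (fit_all_models) {
      fm <- fit_models(long_seq, beh, n_restarts = n_restarts,
                       seed = seeds[3L * r])
      fit <- fm$fits[[model]]
      sel[r] <- fm$best
    } else {
      fit <- fit_run(long_seq, beh, model, n_restarts, seeds[3L * r])
    }
    rows[[r]] <- data.frame(
      rep = r,
      true_eta = tp$eta_c, est_eta = unname(fit$params["eta_c"]),
      true_vmod = tp$vmod, est_vmod = unname(fit$params["vmod"]),
      true_a = tp$a, est_a = unname(fit$params["a"]),
      true_tau = tp$tau, est_tau = unname(fit$params["tau"]))
  }
  est <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(c("eta", "vmod", "a", "tau"), function(p) {
    tr <- est[[paste0("true_", p)]]
    ev <- est[[paste0("est_", p)]]
    data.frame(param = p,
               cor = if (sd(tr) > 0 && sd(ev) > 0) cor(tr, ev) else NA_real_,
               bias = mean(ev - tr),
               rmse = sqrt(mean((ev - tr)^2)))
  }))
  out <- list(estimates = est, summary = summ,
              n_trials = n_concat * config$n_trials)
  if (fit_all_models) out$selection <- sel
  structure(out, class = "msl_recovery")
}

#' @export
print.msl_recovery <- function(x, ...) {
  cat("<msl_recovery>", nrow(x$estimates), "replicates at", x$n_trials,
      "trials\n")
  print(transform(x$summary, cor = round(cor, 3), bias = round(bias, 3),
                  rmse = round(rmse, 3)))
  invisible(x)
}

#' Model recovery simulation
#'
#' Simulates replicates from a generating variant and records which
#' variant wins the per-run BIC comparison.
#'
#' @inheritParams parameter_recovery
#' @param gen_model generating variant.
#' @param anchor population anchor used to draw generating parameters
#'   (defaults to the configured variant/group audio-visual anchor).
#' @return list with `selected` (variant per replicate) and `confusion`
#'   (count table).
#' @export
model_recovery <- function(config, n_rep = 20L, n_concat = 1L,
                           gen_model = "simple", n_restarts = 4L,
                           seed = 1L, dt = 1e-3) {
  seeds <- child_seeds(seed, 4L * n_rep)
  sel <- character(n_rep)
  for (r in seq_len(n_rep)) {
    pars <- with_seed(seeds[4L * r - 3L],
                      draw_params(param_anchor(config$variant, config$group,
                                               config$modality), gen_model))
    seqs <- lapply(seq_len(n_concat), function(j)
      design_run(config, seeds[4L * r - 2L] %% 2000000000L + j))
    long_seq <- concat_sequences(seqs)
    beh <- simulate_run(long_seq, pars$rl, pars$ddm, dt = dt,
                        seed = seeds[4L * r - 1L])
    sel[r] <- fit_models(long_seq, beh, n_restarts = n_restarts,
                         seed = seeds[4L * r])$best
  }
  list(selected = sel,
       confusion = table(factor(sel, levels = MSL_MODELS)))
}
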