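# shared fixtures: small configs and runs built in code

mr_cfg <- function(rev = 0.1, ...) task_config("match_recognition",
                                               reversal_rate = rev, ...)
dc_cfg <- function(rev = 0.1, ...) task_config("discriminative_choice",
                                               reversal_rate = rev, ...)

quick_run <- function(cfg = mr_cfg(), seed = 1, eta = 0.4, vmod = 2,
                      a = 2.3, tau = 0.6, model = "simple") {
  seq <- design_run(cfg, seed)
  rl <- if (model == "simple") rl_params("simple", eta_c = eta)
        else rl_params(model, eta_c = eta, eta_o = eta / 2)
  beh <- simulate_run(seq, rl, ddm_params(vmod, a, tau), seed = seed + 1000)
  list(seq = seq, beh = beh, rl = rl, ddm = ddm_params(vmod, a, tau))
}

# a hand-built match-recognition behaviour record
manual_behaviour <- function(cfg, response, rt, feedback) {
  structure(data.frame(trial = seq_along(response) - 1L,
                       response = response, rt = rt, feedback = feedback,
                       stringsAsFactors = FALSE),
            config = cfg, class = c("msl_behaviour", "data.frame"))
}
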