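test_that("BIC follows the definition", {
  expect_equal(bic(-50, 4, 42), 4 * log(42) + 100)
  expect_lt(bic(-50, 4, 42), bic(-50, 5, 42))
  # differences depend only on delta-logL and delta-k at fixed N
  d1 <- bic(-50, 4, 42) - bic(-45, 5, 42)
  d2 <- bic(-30, 4, 42) - bic(-25, 5, 42)
  expect_equal(d1, d2)
})

test_that("the likelihood is additive over trials", {
  run <- quick_run(mr_cfg(rev = 0), seed = 4, eta = 0)
  s10 <- run$seq[1:10, ]; attr(s10, "config") <- attr(run$seq, "config")
  b10 <- run$beh[1:10, ]
  # doubled data: same 10 trials twice (eta = 0 keeps drifts constant, so
  # the second copy contributes identical terms)
  s20 <- concat_sequences(list(s10, s10))
  b20 <- rbind(b10, b10); b20$trial <- 0:19
  inc10 <- rep(TRUE, 10); inc20 <- rep(TRUE, 20)
  rl <- rl_params("simple", eta_c = 0); dd <- ddm_params(2, 2.3, 0.4)
  nll1 <- negative_log_likelihood(s10, b10, rl, dd, include = inc10)
  nll2 <- negative_log_likelihood(s20, b20, rl, dd, include = inc20)
  expect_equal(nll2, 2 * nll1)
})

test_that("likelihood composes from the density oracle on a hand case", {
  cfg <- mr_cfg(rev = 0)
  s <- design_run(cfg, 1)[1, ]; attr(s, "config") <- cfg
  beh <- manual_behaviour(cfg, "match", 1.2, "positive")
  rl <- rl_params("simple", eta_c = 0.4); dd <- ddm_params(2, 2.3, 0.4)
  # first trial: V = 0.5 so drift = 0; match = upper boundary
  expected <- -log(dwfpt(1.2 - 0.4, 0, 2.3, boundary = "upper"))
  expect_equal(negative_log_likelihood(s, beh, rl, dd, include = TRUE),
               expected)
  # invalid parameters hit the barrier
  expect_equal(negative_log_likelihood(s, beh, rl,
                 structure(list(vmod = 2, a = -1, tau = 0.4, z = 0.5),
                           class = "msl_ddm_params"), include = TRUE), Inf)
})

test_that("on average the truth beats a distant parameter point", {
  set.seed(8)
  wins <- replicate(25, {
    run <- quick_run(mr_cfg(), seed = sample.int(1e6, 1), eta = 0.4,
                     vmod = 2, a = 2.3, tau = 0.6)
    truth <- negative_log_likelihood(run$seq, run$beh,
                                     rl_params("simple", eta_c = 0.4),
                                     ddm_params(2, 2.3, 0.6))
    far <- negative_log_likelihood(run$seq, run$beh,
                                   rl_params("simple", eta_c = 0.05),
                                   ddm_params(8, 1.2, 0.2))
    truth < far
  })
  expect_gt(mean(wins), 0.8)
})

test_that("fitting is deterministic, respects bounds, and flags omission-heavy runs", {
  run <- quick_run(mr_cfg(), seed = 10)
  f1 <- fit_run(run$seq, run$beh, "simple", n_restarts = 3, seed = 5)
  f2 <- fit_run(run$seq, run$beh, "simple", n_restarts = 3, seed = 5)
  expect_identical(f1$params, f2$params)
  b <- default_bounds(run$beh, 1L, "simple")
  expect_true(all(f1$params >= b$lower & f1$params <= b$upper))
  expect_equal(f1$BIC, bic(f1$logL, f1$n_params, f1$n_trials_used))
  expect_true(is.finite(f1$logL))
  # tau upper bound tracks the fastest response
  expect_lte(f1$params["tau"], min(run$beh$rt, na.rm = TRUE))
  # omission-heavy run only warns
  beh_om <- run$beh
  beh_om$response[1:12] <- NA; beh_om$rt[1:12] <- NA
  beh_om$feedback[1:12] <- "neutral"
  expect_warning(fit_run(run$seq, beh_om, "simple", n_restarts = 1,
                         seed = 1), "omission")
})

test_that("the likelihood surface is finite across the bounded box", {
  run <- quick_run(mr_cfg(), seed = 14)
  b <- default_bounds(run$beh, 1L, "simple")
  corners <- expand.grid(eta_c = c(0, 1), vmod = c(0, 20), a = c(0.3, 5),
                         tau = c(0.1, b$upper["tau"]))
  for (i in seq_len(nrow(corners))) {
    nll <- negative_log_likelihood(run$seq, run$beh,
             rl_params("simple", eta_c = corners$eta_c[i]),
             ddm_params(corners$vmod[i], corners$a[i], corners$tau[i]))
    expect_true(is.finite(nll))
  }
})

test_that("model selection minimises BIC with ties to the simpler model", {
  mk <- function(model, logL, k) structure(
    list(model = model, logL = logL, n_params = k,
         BIC = bic(logL, k, 42)), class = "msl_fit")
  fits <- list(simple = mk("simple", -50, 4),
               transfer = mk("transfer", -45, 5))
  expect_equal(select_model(fits), "transfer")
  # single model fitted: it is selected
  expect_equal(select_model(fits["simple"]), "simple")
  # exact BIC tie: fewer parameters win
  tied <- list(transfer = mk("transfer", -50, 5),
               simple = mk("simple", -50 - log(42) / 2, 4))
  expect_equal(tied$simple$BIC, tied$transfer$BIC)
  expect_equal(select_model(tied), "simple")
  tab <- model_count_table(c("simple", "simple", "transfer"),
                           c("av", "av", "tv"))
  expect_equal(sum(tab), 3)
  expect_equal(unname(tab["simple", "av"]), 2)
})

test_that("parameter recovery improves with trial count", {
  set.seed(303)
  tp <- data.frame(eta_c = mslrl:::rtruncnorm(8, 0.38, 0.33, 0.05, 1),
                   vmod = mslrl:::rtruncnorm(8, 2, 1.5, 0.3, 8),
                   a = mslrl:::rtruncnorm(8, 2.48, 0.42, 0.5, 4),
                   tau = mslrl:::rtruncnorm(8, 0.7, 0.3, 0.15, 1.2))
  short <- parameter_recovery(mr_cfg(), tp, n_concat = 1, n_restarts = 3,
                              seed = 5)
  long <- parameter_recovery(mr_cfg(), tp, n_concat = 10, n_restarts = 3,
                             seed = 5)
  expect_equal(short$n_trials, 42)
  expect_equal(long$n_trials, 420)
  expect_equal(nrow(long$estimates), 8)
  # consistency with n: every parameter's RMSE shrinks
  expect_true(all(long$summary$rmse <= short$summary$rmse))
})
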