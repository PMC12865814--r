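test_that("trial filtering applies the omission, 200 ms and 3 SD rules", {
  cfg <- mr_cfg()
  # an outlier only exceeds 3 within-run SDs with enough regular trials
  rts <- c(0.15, rep(c(0.5, 0.6, 0.55, 0.65), 9), 6.0)
  n <- length(rts)
  beh <- manual_behaviour(cfg, rep("match", n), rts, rep("positive", n))
  beh$response[5] <- NA; beh$rt[5] <- NA; beh$feedback[5] <- "neutral"
  fl <- filter_trials(beh)
  expect_equal(fl$log$rule[fl$log$trial == 0], "rt_min")
  expect_equal(fl$log$rule[fl$log$trial == 4], "omission")
  # hand check of the outlier rule on the surviving set
  surv1 <- rts[-c(1, 5)]
  expect_true(6.0 > mean(c(surv1)) + 3 * sd(c(surv1)))
  expect_equal(fl$log$rule[fl$log$trial == n - 1], "rt_sd")
  expect_equal(nrow(fl$data), n - 3)
  # accounting: excluded + surviving = all trials
  expect_equal(nrow(fl$data) + nrow(fl$log), n)
  expect_false(fl$run_excluded)
})

test_that("clean runs pass through untouched", {
  cfg <- mr_cfg()
  beh <- manual_behaviour(cfg, rep("match", 10), rep(0.8, 10),
                          rep("positive", 10))
  fl <- filter_trials(beh)
  expect_equal(nrow(fl$data), 10)
  expect_equal(nrow(fl$log), 0)
})

test_that("runs with more than 20% omissions are flagged", {
  cfg <- mr_cfg()
  mk <- function(n_om) {
    resp <- rep("match", 42); rt <- rep(0.8, 42); fb <- rep("positive", 42)
    if (n_om > 0) {
      resp[seq_len(n_om)] <- NA; rt[seq_len(n_om)] <- NA
      fb[seq_len(n_om)] <- "neutral"
    }
    manual_behaviour(cfg, resp, rt, fb)
  }
  expect_true(filter_trials(mk(9))$run_excluded)   # 21.4% > 20%
  expect_false(filter_trials(mk(8))$run_excluded)  # 19.0%
})

test_that("bins partition runs into the documented thirds", {
  expect_equal(as.vector(table(mslrl:::bin_index(0:41, 42))), c(14L, 14L, 14L))
  expect_equal(as.vector(table(mslrl:::bin_index(0:43, 44))), c(15L, 15L, 14L))
  run <- quick_run(dc_cfg(), seed = 3)
  tr <- run_model(run$seq, run$beh, run$rl, 2)
  b <- bin_summaries(run$seq, run$beh, tr)
  expect_equal(b$bin, 1:3)
  expect_true(all(b$accuracy >= 0 & b$accuracy <= 1, na.rm = TRUE))
  expect_true(all(b$mean_abs_drift >= 0))
})

test_that("an all-correct run has ceiling accuracy in every bin", {
  cfg <- mr_cfg()
  s <- design_run(cfg, 4)
  beh <- manual_behaviour(cfg, ifelse(s$is_match, "match", "nonmatch"),
                          rep(0.8, 42), rep("positive", 42))
  b <- bin_summaries(s, beh)
  expect_equal(b$accuracy, rep(1, 3))
  expect_equal(b$mean_rt, rep(0.8, 3))
})

test_that("empty bins yield missing summaries, not zero", {
  cfg <- mr_cfg()
  resp <- rep(c("match", NA), times = c(28, 14))
  rt <- c(rep(0.8, 28), rep(NA, 14))
  fb <- rep(c("positive", "neutral"), times = c(28, 14))
  beh <- manual_behaviour(cfg, resp, rt, fb)
  b <- suppressWarnings(bin_summaries(design_run(cfg, 4), beh))
  expect_true(is.na(b$accuracy[3]))
  expect_true(is.na(b$mean_rt[3]))
})

test_that("reaction-time/surprise regression recovers a planted slope", {
  cfg <- mr_cfg()
  beta <- 0.25
  runs <- mslrl:::with_seed(77, lapply(1:12, function(i) {
    s <- design_run(cfg, 500 + i)
    sur <- surprise_trace(s)
    rt <- 0.6 + beta * sur$surprise + rnorm(42, 0, 0.08)
    list(behaviour = manual_behaviour(cfg, rep("match", 42), rt,
                                      rep("positive", 42)),
         surprise = sur)
  }))
  res <- rt_surprise_association(runs)
  expect_equal(nrow(res$slopes), 12)
  ci <- res$test$mean_slope +
    c(-1, 1) * qt(0.975, res$test$df) * sd(res$slopes$slope) / sqrt(12)
  expect_true(beta > ci[1] && beta < ci[2])
  expect_lt(res$test$p, 0.01)
})

test_that("degenerate regressions are skipped and slopes ignore RT shifts", {
  cfg <- mr_cfg()
  s <- design_run(cfg, 9)
  sur <- surprise_trace(s)
  const <- sur; const$surprise <- rep(1, 42)
  beh <- manual_behaviour(cfg, rep("match", 42),
                          mslrl:::with_seed(1, runif(42, 0.5, 1.5)),
                          rep("positive", 42))
  expect_warning(res <- rt_surprise_association(
    list(list(behaviour = beh, surprise = const))), "zero variance")
  expect_equal(nrow(res$slopes), 0)
  # fewer than five surviving trials: skipped
  tiny <- manual_behaviour(cfg, c(rep("match", 3), rep(NA, 39)),
                           c(rep(0.8, 3), rep(NA, 39)),
                           c(rep("positive", 3), rep("neutral", 39)))
  expect_warning(rt_surprise_association(
    list(list(behaviour = tiny, surprise = sur))), "fewer than")
  # slope invariance to adding a constant to all RTs
  s1 <- rt_surprise_association(beh, sur)$slopes$slope
  beh2 <- beh; beh2$rt <- beh2$rt + 10
  s2 <- rt_surprise_association(beh2, sur)$slopes$slope
  expect_equal(s1, s2)
})

test_that("regressor export follows the inclusion rules of the modulators", {
  run <- quick_run(mr_cfg(), seed = 21)
  s <- run$seq; beh <- run$beh
  # force one omission and one extreme outlier
  beh$response[5] <- NA; beh$rt[5] <- NA; beh$feedback[5] <- "neutral"
  beh$rt[10] <- 0.05
  tr <- run_model(s, beh, run$rl, 2)
  sur <- surprise_trace(s)
  fl <- filter_trials(beh)
  reg <- export_regressors(s, beh, tr, sur, fl)
  # surprise covers ALL trials regardless of behaviour
  expect_equal(nrow(reg$stimulus_surprise), 42)
  # feedback events: included + neutral + outliers partition the run
  expect_equal(nrow(reg$feedback_rpe) + nrow(reg$neutral) +
               nrow(reg$rt_outliers), 42)
  expect_equal(nrow(reg$feedback_rpe), nrow(fl$data))
  # the omission (row 5) feeds the neutral regressor, never the RPE one
  expect_true(s$onset_feedback[5] %in% reg$neutral$onset)
  expect_false(s$onset_feedback[5] %in% reg$feedback_rpe$onset)
  expect_true(s$onset_feedback[10] %in% reg$rt_outliers$onset)
  # exact set equality with the filter decision
  expect_setequal(reg$feedback_rpe$onset, s$onset_feedback[
    beh$trial %in% fl$data$trial])
  # modulators are mean-centred per run
  expect_equal(mean(reg$stimulus_surprise$weight), 0, tolerance = 1e-12)
  expect_equal(mean(reg$feedback_rpe$weight), 0, tolerance = 1e-12)
})

test_that("events.tsv round-trips onsets exactly", {
  run <- quick_run(mr_cfg(), seed = 22)
  tr <- run_model(run$seq, run$beh, run$rl, 2)
  sur <- surprise_trace(run$seq)
  dir <- tempfile()
  reg <- export_regressors(run$seq, run$beh, tr, sur, dir = dir)
  expect_true(file.exists(file.path(dir, "events.tsv")))
  back <- read.delim(file.path(dir, "events.tsv"), na.strings = "n/a")
  expect_equal(back$onset, reg$events$onset)
  expect_equal(nrow(back), 2 * 42)
  # accuracy with omissions excluded never falls below the all-trial rate
  beh <- run$beh
  correct <- !is.na(beh$response) &
    beh$response == ifelse(run$seq$is_match, "match", "nonmatch")
  acc_ex <- sum(correct) / sum(!is.na(beh$response))
  acc_in <- sum(correct) / nrow(beh)
  expect_gte(acc_ex, acc_in)
})

test_that("regressor export requires onsets", {
  cfg <- mr_cfg()
  s <- make_trial_sequence(cfg, 1)
  beh <- manual_behaviour(cfg, rep("match", 42), rep(0.8, 42),
                          rep("positive", 42))
  tr <- run_model(s, beh, rl_params("simple", eta_c = 0.3), 2)
  expect_error(export_regressors(s, beh, tr, surprise_trace(s)), "onsets")
})
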