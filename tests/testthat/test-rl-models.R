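test_that("reward prediction error is R minus V", {
  expect_equal(reward_prediction_error(1, 0.5), 0.5)
  expect_equal(reward_prediction_error(0, 0), 0)
  expect_equal(reward_prediction_error(1, 0.675), 0.325)
  expect_error(reward_prediction_error(2, 0.5))
})

test_that("odds-ratio normalisation matches hand evaluation and sums to one", {
  nv <- normalize_values(0.8, 0.6)
  expect_equal(nv$c, 0.32 / 0.44)
  expect_equal(nv$c + nv$o, 1)
  # symmetry: equal values are indifferent
  for (v in c(0.1, 0.5, 0.9))
    expect_equal(normalize_values(v, v)$c, 0.5)
  # extreme dominance limit under the clamp
  expect_gt(normalize_values(1, 0)$c, 1 - 1e-5)
  # order consistency under random values
  vals <- mslrl:::with_seed(2, matrix(runif(200), ncol = 2))
  nc <- normalize_values(vals[, 1], vals[, 2])$c
  expect_equal(nc > 0.5, vals[, 1] > vals[, 2])
})

test_that("drift rate mapping follows the two task rules", {
  expect_equal(drift_rate(0.75, vmod = 2, variant = "match_recognition"), 1)
  expect_equal(drift_rate(0.5, 0.5, vmod = 3,
                          variant = "discriminative_choice"), 0)
  d1 <- drift_rate(0.8, 0.3, vmod = 2, variant = "discriminative_choice")
  d2 <- drift_rate(0.3, 0.8, vmod = 2, variant = "discriminative_choice")
  expect_equal(d1, -d2)
  expect_gt(d1, 0)
})

test_that("forward traces equal a step-by-step hand replay for all variants", {
  etas <- list(ecp = 0.5, ecn = 0.2, eop = 0.3, eon = 0.1)
  grid <- expand.grid(variant = c("match_recognition",
                                  "discriminative_choice"),
                      model = c("simple", "simple_asym", "transfer",
                                "transfer_asym"),
                      stringsAsFactors = FALSE)
  for (i in seq_len(nrow(grid))) {
    cfg <- task_config(grid$variant[i], reversal_rate = 0.1)
    run <- quick_run(cfg, seed = 40 + i)
    rl <- switch(grid$model[i],
      simple = rl_params("simple", eta_c = etas$ecp),
      simple_asym = rl_params("simple_asym", eta_c_pos = etas$ecp,
                              eta_c_neg = etas$ecn),
      transfer = rl_params("transfer", eta_c = etas$ecp, eta_o = etas$eop),
      transfer_asym = if (grid$variant[i] == "discriminative_choice")
        rl_params("transfer_asym", eta_c_pos = etas$ecp,
                  eta_c_neg = etas$ecn, eta_o_pos = etas$eop,
                  eta_o_neg = etas$eon)
      else rl_params("transfer_asym", eta_c_pos = etas$ecp,
                     eta_c_neg = etas$ecn, eta_o = etas$eop))
    tr <- run_model(run$seq, run$beh, rl, 2)
    e4 <- mslrl:::eta_vector(rl)
    orc <- rw_oracle(run$seq, run$beh, grid$model[i],
                     list(ecp = e4[1], ecn = e4[2], eop = e4[3],
                          eon = e4[4]), 2)
    expect_equal(tr$drift, orc$drift, tolerance = 1e-12,
                 info = paste(grid$variant[i], grid$model[i]))
    expect_equal(tr$RPE, orc$rpe, tolerance = 1e-12)
  }
})

test_that("a zero learning rate freezes values at the unbiased prior", {
  run <- quick_run(mr_cfg(), seed = 3)
  tr <- run_model(run$seq, run$beh, rl_params("simple", eta_c = 0), 2)
  expect_true(all(tr$V_chosen[!is.na(tr$V_chosen)] == 0.5))
  expect_true(all(tr$drift == 0))
  resp <- !is.na(run$beh$response) & run$beh$feedback != "neutral"
  R <- as.integer(run$beh$feedback[resp] == "positive")
  Rp <- as.integer((run$beh$response[resp] == "match") == (R == 1))
  expect_equal(tr$RPE[resp], Rp - 0.5)
})

test_that("a unit learning rate jumps the value to the outcome", {
  cfg <- mr_cfg(rev = 0)
  beh <- manual_behaviour(cfg, c("match", "match"), c(1, 1),
                          c("positive", "positive"))
  s <- design_run(cfg, 1)[1:2, ]
  s$audio_tactile <- c("A", "A"); s$visual <- c("0", "0")
  s$is_match <- TRUE
  attr(s, "config") <- cfg
  tr <- run_model(s, beh, rl_params("simple", eta_c = 1), 1)
  expect_equal(tr$V_chosen, c(0.5, 1))
  expect_equal(tr$drift, c(0, 1))
})

test_that("asymmetric variants with equal rates reproduce the symmetric traces exactly", {
  for (variant in c("match_recognition", "discriminative_choice")) {
    run <- quick_run(task_config(variant, reversal_rate = 0.1), seed = 77)
    t_sym <- run_model(run$seq, run$beh, rl_params("simple", eta_c = 0.37), 2)
    t_asym <- run_model(run$seq, run$beh,
                        rl_params("simple_asym", eta_c_pos = 0.37,
                                  eta_c_neg = 0.37), 2)
    expect_identical(t_sym, t_asym)
    t_tr <- run_model(run$seq, run$beh,
                      rl_params("transfer", eta_c = 0.37, eta_o = 0.21), 2)
    t_tra <- run_model(run$seq, run$beh, if (variant == "match_recognition")
      rl_params("transfer_asym", eta_c_pos = 0.37, eta_c_neg = 0.37,
                eta_o = 0.21)
      else rl_params("transfer_asym", eta_c_pos = 0.37, eta_c_neg = 0.37,
                     eta_o_pos = 0.21, eta_o_neg = 0.21), 2)
    expect_identical(t_tr, t_tra)
  }
})

test_that("transfer moves the other pair opposite to the chosen pair", {
  cfg <- dc_cfg(rev = 0)
  s <- make_trial_sequence(cfg, 2)
  beh <- manual_behaviour(cfg, rep(NA_character_, nrow(s)),
                          rep(NA_real_, nrow(s)), rep("neutral", nrow(s)))
  # answer the first trial correctly (choose the matching side)
  beh$response[1] <- s$correct_side[1]
  beh$rt[1] <- 1
  beh$feedback[1] <- "positive"
  tr <- run_model(s, beh, rl_params("transfer", eta_c = 0.5, eta_o = 0.5), 2)
  # find the next trial reusing either presented pair
  m <- pairing_frequency_table(cfg)$matching
  s1 <- s$audio_tactile[1]
  chosen_v <- m[s1]
  other_v <- setdiff(c(s$visual_left[1], s$visual_right[1]), chosen_v)
  later_c <- which(s$audio_tactile == s1 &
                   (s$visual_left == chosen_v | s$visual_right == chosen_v))[2]
  expect_true(is.finite(later_c))
  sa <- mslrl:::seq_arrays(s)
  ba <- mslrl:::behaviour_arrays(beh, 0L)
  out <- mslrl:::forward_cpp(0L, 2L, 4L, 4L, sa$at, sa$vm, sa$vo, sa$side,
                             ba$resp, ba$fb,
                             mslrl:::eta_vector(rl_params("transfer",
                               eta_c = 0.5, eta_o = 0.5)), 2)
  V <- matrix(out$v_final, 4, 4, byrow = TRUE)
  expect_equal(V[match(s1, LETTERS), match(chosen_v, as.character(0:3))],
               0.75) # 0.5 + 0.5*(1-0.5)
  expect_equal(V[match(s1, LETTERS), match(other_v, as.character(0:3))],
               0.25) # moved toward 1-R = 0
})

test_that("values stay within the unit interval for random runs", {
  for (seed in 1:5) {
    run <- quick_run(mr_cfg(), seed = 200 + seed, eta = 0.95,
                     model = "transfer")
    sa <- mslrl:::seq_arrays(run$seq)
    ba <- mslrl:::behaviour_arrays(run$beh, 1L)
    out <- mslrl:::forward_cpp(1L, 2L, 3L, 3L, sa$at, sa$vm, sa$vo, sa$side,
                               ba$resp, ba$fb, rep(0.95, 4), 2)
    expect_true(all(out$v_final >= 0 & out$v_final <= 1))
    ok <- !is.na(out$rpe)
    expect_true(all(abs(out$rpe[ok]) <= 1))
  }
})

test_that("traces are causal: truncating the run leaves the prefix unchanged", {
  run <- quick_run(mr_cfg(), seed = 31)
  full <- run_model(run$seq, run$beh, run$rl, 2)
  half_seq <- run$seq[1:20, ]
  attr(half_seq, "config") <- attr(run$seq, "config")
  half <- run_model(half_seq, run$beh[1:20, ], run$rl, 2)
  expect_equal(full[1:20, ], half, ignore_attr = TRUE)
})
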