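# independent oracles, deliberately written differently from the package
# implementations

# brute-force recount of Laplace-smoothed probabilities: at trial t, count
# occurrences of the trial's key over trials 0..t-1 from scratch
surprise_oracle <- function(keys, n) {
  sapply(seq_along(keys), function(t) {
    hits <- if (t == 1) 0 else sum(keys[seq_len(t - 1)] == keys[t])
    (1 + hits) / (n + (t - 1))
  })
}

# step-by-step Rescorla-Wagner replay in plain R
# etas: list(ecp, ecn, eop, eon); returns per-trial drift/V_chosen/RPE
rw_oracle <- function(seq, beh, model, etas, vmod) {
  cfg <- attr(seq, "config")
  nat <- cfg$n_audio_tactile; nvis <- cfg$n_visual
  V <- matrix(0.5, nat, nvis,
              dimnames = list(LETTERS[1:nat], as.character(0:(nvis - 1))))
  n <- nrow(seq)
  drift <- vch <- rpe <- rep(NA_real_, n)
  transfer <- model %in% c("transfer", "transfer_asym")
  for (t in 1:n) {
    if (cfg$variant == "discriminative_choice") {
      s <- seq$audio_tactile[t]
      vl <- seq$visual_left[t]; vr <- seq$visual_right[t]
      nv <- normalize_values(V[s, vl], V[s, vr])
      drift[t] <- (nv$c - nv$o) * vmod
      r <- beh$response[t]
      if (!is.na(r)) {
        cv <- if (r == "left") vl else vr
        ov <- if (r == "left") vr else vl
        vch[t] <- V[s, cv]
        R <- switch(beh$feedback[t], positive = 1, negative = 0, NA)
        if (!is.na(R)) {
          rpe[t] <- R - V[s, cv]
          ec <- if (R == 1) etas$ecp else etas$ecn
          V[s, cv] <- V[s, cv] + ec * (R - V[s, cv])
          if (transfer) {
            eo <- if (R == 1) etas$eop else etas$eon
            V[s, ov] <- V[s, ov] + eo * ((1 - R) - V[s, ov])
          }
        }
      }
    } else {
      s <- seq$audio_tactile[t]; vv <- seq$visual[t]
      drift[t] <- (2 * V[s, vv] - 1) * vmod
      vch[t] <- V[s, vv]
      r <- beh$response[t]
      R <- switch(beh$feedback[t], positive = 1, negative = 0, NA)
      if (!is.na(r) && !is.na(R)) {
        Rp <- as.integer((r == "match") == (R == 1))
        rpe[t] <- Rp - V[s, vv]
        ec <- if (R == 1) etas$ecp else etas$ecn
        V[s, vv] <- V[s, vv] + ec * (Rp - V[s, vv])
        if (transfer && R == 1) {
          for (i in rownames(V)) for (j in colnames(V))
            if ((i == s || j == vv) && !(i == s && j == vv))
              V[i, j] <- V[i, j] - etas$eop * V[i, j]
        }
      } else vch[t] <- V[s, vv]
    }
  }
  list(drift = drift, v_chosen = vch, rpe = rpe, V = V)
}

# fixed-term series evaluation of the first-passage density (lower
# boundary), independent of the adaptive implementation: large-time sine
# series with 500 terms, or small-time reflection series with 50 images
wfpt_series_oracle <- function(t, v, a, w, form = c("large", "small")) {
  form <- match.arg(form)
  u <- t / a^2
  if (form == "large") {
    k <- 1:500
    f1 <- pi * sum(k * exp(-k^2 * pi^2 * u / 2) * sin(k * pi * w))
  } else {
    k <- -50:50
    f1 <- sum((w + 2 * k) * exp(-(w + 2 * k)^2 / (2 * u))) /
      sqrt(2 * pi * u^3)
  }
  f1 / a^2 * exp(-v * a * w - v^2 * t / 2)
}

# analytic probability of absorption at the lower boundary
p_lower_oracle <- function(v, a, z = 0.5) {
  if (abs(v) < 1e-12) return(1 - z)
  (exp(-2 * v * a * (1 - z)) - 1) /
    (exp(-2 * v * a * (1 - z)) - exp(2 * v * a * z))
}
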