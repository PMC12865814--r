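---
title: "Methods: task structure, surprise, and the reinforcement-learning diffusion model"
author: "mslrl"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: task structure, surprise, and the reinforcement-learning diffusion model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mslrl)
```

This vignette is the package's own account of the science it implements:
the two multisensory learning task designs, the Shannon-surprise model of
statistical learning, the Rescorla–Wagner/diffusion generative model of
choices and reaction times, the fitting and model-selection machinery,
and the behavioural/neuroimaging post-processing. It also records the
numerical choices and the places where the design was genuinely open.

## Task structure

Both task variants pair visual symbols with sounds (audio–visual runs) or
vibration patterns (tactile–visual runs).

* **Discriminative choice**: 4 auditory/tactile × 4 visual stimuli,
  44 trials per run. Two symbols appear; the side showing the partner of
  the presented sound/vibration must be chosen. Each sound occurs in 11
  trials and its matching symbol is shown on *all* of them, so the trial
  identity is carried by the non-matching partner, which follows a cyclic
  7/3/1 schedule over the three other visuals (63.6 %, 27.3 %, 9.1 % of
  each sound's trials). Every visual stimulus appears in 22 trials.
* **Match recognition**: 3 × 3 stimuli, 42 trials. A single pair is
  judged match vs non-match. Each sound occurs 14 times: 7 with its
  matching visual (50 %), 5 with a frequent non-matching partner
  (35.7 %) and 2 with a rare one (14.3 %), again cyclically.

`pairing_frequency_table()` builds these count tables;
`make_trial_sequence()` realises them exactly for every seed and
counterbalances the correct side in the discriminative choice task
(22 left / 22 right; per sound 6/5 or 5/6, the odd counts make an exact
split impossible). We impose no further order constraints (e.g. no
repetition limits), as none are part of the schedule.

**Feedback reversal.** A scheduled fraction (0, 5, 10 or 20 %) of trials
deliver inverted feedback valence. The count is `round(rate × n_trials)`
(ties up), allocated round-robin over the auditory/tactile stimuli in
random order so per-stimulus counts differ by at most one — the even
allocation the design calls for. Omissions always receive neutral
feedback.

**Timing.** Each trial is ITI → stimulus (2 s) → ISI → feedback (1.8 s
children, 2 s adults). ITI/ISI are gamma distributed with printed means
and ranges (discriminative choice: ITI 1.87 s [0.76–3.45], ISI 3.45 s
[2.28–4.83]; match recognition children: 2.05/[0.76–3.45] and
3.28/[2.04–4.90]; adults: 2.06/[0.79–3.39] and 2.67/[1.11–4.34]).
These durations reproduce the printed total run lengths
(44 × (1.87 + 2 + 3.45 + 1.8) ≈ 401 s; 42 × 9.13 ≈ 383 s children;
42 × 8.73 ≈ 367 s adults), which is how the onset model was validated.
Only the mean and range of the interval distributions are given, so a
parametric choice is needed: we fix the gamma shape at 4 (coefficient of
variation 0.5, a typical jitter width for event-related designs) and
solve the scale by root finding so that the mean *after truncation to the
printed range* equals the printed mean; truncation is by rejection.
Solving the scale from the untruncated mean instead would bias the
realised mean by up to 6 % for the adult intervals, which is why the
calibrated form is used — `sample_timing()` keeps the realised mean
within the 2 % contract checked in the tests.

## Shannon surprise

The probability of the trial-\(t\) combination is the Laplace-smoothed
relative frequency \(p(x_t) = (1 + c_t(x_t)) / (n + t)\), where
\(c_t(x)\) counts previous occurrences, so the first trial has
\(p = 1/n\) and surprise \(I_t = -\ln p(x_t)\) starts at \(\ln n\).
Natural logarithms are used throughout; the base only rescales
regressions and regressors linearly.

Combination spaces: \(n = 9\) pairs (match recognition); \(n = 16\) for
the discriminative-choice triplet event (sound plus both visuals,
unordered — left/right placement carries no statistical structure); and a
non-matching variant with \(n = 4\) that tracks only the (sound,
non-matching visual) pair, because the matching symbol is always present
and carries no surprise. The triplet count of 16 is kept as specified by
the source design even though only 12 distinct triplets are realisable
(4 sounds × 3 non-matching partners); the 4 virtual combinations simply
retain their smoothing mass. `surprise_trace(seq, n_override = 12)`
provides the sensitivity analysis.

## The generative model

**Values and prediction errors.** All pair values start at 0.5
(uninformed, unbiased). After feedback \(R \in \{0, 1\}\) the
chosen/presented pair is updated by \(V \leftarrow V + \eta (R' - V)\)
and the reward prediction error is \(R' - V\) (pre-update). In the
discriminative choice task the learning signal is the delivered feedback
itself, \(R' = R\). In the match recognition task the pair value is read
as match evidence, so the signal is recoded:
\(R' = 1\) iff the response agreed with the feedback sign
("match" confirmed or "non-match" disconfirmed). This keeps \(V\)
interpretable as the probability that the pair is matching, consistent
with the drift mapping below; the plain delta rule is ambiguous here
because a correct "non-match" response must *lower* the pair's value.

**Variants.** Four learning rules: `simple`; `simple_asym` with separate
\(\eta^+/\eta^-\) selected by the delivered feedback valence; `transfer`,
which additionally moves the *other* presented pair toward the
complement \(1 - R\) (discriminative choice) or, after positive feedback
only, moves every pair sharing a stimulus with the presented pair toward
0 (match recognition — a confirmed match rules the overlapping pairs
out); and `transfer_asym` (four rates in the discriminative choice task,
three in match recognition, where transfer only fires after positive
feedback). The complement target is deliberate: value transfer expresses
that evidence *for* the chosen association is evidence *against* the
competing ones, and the asymmetric-equal-rates case collapses exactly
onto the symmetric variants (a bit-level test).

**Drift.** Discriminative choice uses the odds-ratio normalisation
\(\bar V^C = V^C(1-V^O) / [V^C(1-V^O) + V^O(1-V^C)]\) of the two
presented pairs (clamped to \([10^{-6}, 1-10^{-6}]\) to avoid 0/0 at the
extremes; the clamp is far below fitting precision) and
\(v_t = (\bar V^C - \bar V^O)\, v_{mod}\). Match recognition uses the
raw value: \(v_t = (2 V - 1)\, v_{mod}\). Normalisation is a
two-option construct and is not applied in the single-pair task.

**Choice and reaction time.** Responses follow a Wiener diffusion with
boundary separation \(a\), non-decision time \(\tau\), and relative
starting point fixed at \(z = 0.5\) (no response bias; never fitted).
The option frame is fixed *before* the choice: upper boundary = "left"
(discriminative choice) or "match" (match recognition), and the drift is
computed in that frame (left-minus-right, match-minus-nonmatch). The
likelihood of a response at time \(t\) is the first-passage density

\[
f(t \mid v, a, z) = \frac{\pi}{a^2}
  e^{-v a z - v^2 t / 2}
  \sum_{k \ge 1} k\, e^{-k^2 \pi^2 t / (2 a^2)} \sin(k \pi z),
\]

for the lower boundary, with the upper boundary via
\((v, z) \to (-v, 1-z)\).

## Numerical choices

* **Series evaluation.** The sine series converges slowly for small
  \(t/a^2\); the implementation switches adaptively between it and the
  standard small-time (image-reflection) expansion, choosing whichever
  needs fewer terms for a truncation error below \(10^{-8}\). Both
  representations are checked against fixed 500-/101-term reference sums
  and against numerical quadrature (unit total mass to \(10^{-4}\), exact
  analytic absorption probabilities to \(10^{-6}\)).
* **Sampling.** The forward sampler integrates \(dX = v\,dt + dW\) by
  Euler–Maruyama with a Brownian-bridge correction for undetected
  within-step boundary crossings, which removes the leading
  discrete-monitoring bias; at \(dt = 10^{-3}\) s the sampled histograms
  agree with the density within Monte-Carlo error at \(2 \times 10^5\)
  paths (the simulation default; \(dt\) is a user parameter).
* **Degenerate inputs.** Reaction times at or below \(\tau\) get a floor
  likelihood of \(10^{-10}\) so the optimisation surface stays finite;
  such trials are essentially eliminated beforehand by the 200 ms filter.
  Invalid parameter vectors return \(+\infty\).
* **Likelihood trials vs learning trials.** Omissions and RT-filtered
  trials contribute no likelihood terms, but their feedback still drives
  the value updates — learning happened on those trials regardless of
  measurement quality. Omissions (neutral feedback) never update values.

## Fitting, model selection, recovery

Per run and variant, the free parameters (learning rates in \([0,1]\),
\(v_{mod} \in [0, 20]\), \(a \in [0.3, 5]\),
\(\tau \in [0.1, \min \mathrm{RT} - 0.01]\); bounds chosen to cover the
empirically plausible ranges with wide margins) are estimated by
multi-start bounded quasi-Newton minimisation of the negative
log-likelihood: one anchor start at a plausible interior point plus
uniformly drawn restarts (8 by default), all seeded. On this smooth
4–7-dimensional surface the multi-start scheme reliably reaches the
global optimum — the optimum, not the optimiser, is the contract, and
refits under a fixed seed are bit-reproducible. Variants are compared by
\(\mathrm{BIC} = k \ln N - 2 \ln \hat L\) with \(N\) the likelihood trial
count; ties go to the model with fewer parameters.

`parameter_recovery()` and `model_recovery()` close the loop: simulate at
known parameters, refit, and summarise correlation/bias/RMSE and the
selection confusion. At 420 trials per fit (ten concatenated run
designs) the recovery correlations exceed 0.94 for the boundary and
non-decision time and 0.98 for the learning rate and drift weight under
the study-condition parameter distributions, and data generated from the
simple variant select it in the vast majority of replicates; at a single
42-trial run the estimates are markedly noisier — which is precisely why
recovery analyses at both scales ship with the package. Validation sizes
used by the test-suite: 50 recovery replicates at 420 and 42 trials,
50 model-recovery replicates, \(2\times10^5\)-path sampler checks on a
five-point \((v, a, \tau)\) grid spanning the plausible parameter ranges.

## The synthetic-data generator

`simulate_run()` composes the generative model forward: drift from the
current values, a first-passage draw, omission if the reaction time
exceeds the response window (stimulus duration plus the trial's ISI —
responding is possible until feedback onset; the experiment's exact
deadline is not documented, so presentation timing defines it), feedback
by correctness and the reversal schedule, then the value update.
`simulate_cohort()` draws per-subject parameters from truncated-normal
population distributions anchored on the published per-group parameter
means and SDs (e.g. adult audio–visual match recognition: learning rate
0.35 (0.28), non-decision time 0.69 s (0.20), drift weight 3.60 (3.30),
boundary 2.32 (0.41)), truncated to the admissible ranges above.

What the generator emulates: the exact pairing-frequency structure,
reversal schedule, timing distributions, omission mechanics, and
choice/RT behaviour consistent with the fitted model class. What it does
not: lapses and fatigue, attention drift, motor-noise differences beyond
\(\tau\), stimulus-complexity effects (complexity labels are metadata
only), and any departure of real decision dynamics from the Wiener
first-passage form. Passing tests therefore demonstrate *internal*
consistency (the pipeline recovers what generated the data) — not that
real behaviour obeys the model.

## Behavioural analysis and regressor export

`filter_trials()` removes omissions, reaction times under 200 ms, and —
in a single pass, on the mean/SD of the trials surviving the first two
rules — reaction times beyond 3 within-run SDs; whether the original
criterion was iterated is undocumented, and the single pass is the
conservative reading. Runs with more than 20 % omissions are flagged for
exclusion. `bin_summaries()` splits runs into thirds by original trial
index (15/15/14 or 14/14/14) and reports accuracy (correct /
non-omitted), mean correct-trial reaction time, and mean absolute drift.

`rt_surprise_association()` regresses trial-wise reaction times on
surprise per run and t-tests the per-run slopes across runs. This is a
deliberate simplification of a mixed-model analysis — the LMM is standard
methodology rather than part of the computational core; per-run OLS
slopes keep the package dependency-light and the slopes can be handed to
any mixed-model machinery downstream.

`export_regressors()` writes first-level event sets: the surprise
modulator on stimulus onsets for **all** trials (statistical learning is
implicit, so behavioural exclusions do not apply), the prediction-error
modulator on feedback onsets for the filtered trial set only, and two
nuisance regressors (neutral-feedback onsets for omissions, feedback
onsets for RT outliers). Modulators are mean-centred per run, the
standard convention for parametric modulation, before export as
BIDS-style `events.tsv` plus three-column timing files.

## Known limitations

* No inter-trial variability parameters (sv, sz, st), collapsing bounds,
  or hierarchical/group-level estimation.
* The likelihood ignores response-window censoring; with the default
  windows and plausible parameters omissions are rare (&lt; 1–2 %), but
  heavy censoring (very slow parameter regimes) biases the boundary
  estimate downward.
* Identifiability at a single 42-trial run is limited, especially for
  the transfer rates; per-run point estimates at that scale should be
  interpreted through the recovery results shipped with the package.
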