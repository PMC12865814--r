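# mslrl

Model-based analysis of multisensory association learning with a
reinforcement-learning drift-diffusion model (RLDDM).

In developmental studies of multisensory learning, children and adults
learn arbitrary audio–visual and tactile–visual associations (letter-like
symbols paired with sounds or vibration patterns) through trial-by-trial
probabilistic feedback. Two task variants are used: a **discriminative
choice** task (44 trials; two symbols shown, pick the side matching the
sound/vibration; 4 × 4 stimuli) and a **match recognition** task
(42 trials; one pair shown, judge match vs non-match; 3 × 3 stimuli,
50 % matching). Presentation frequencies of the stimulus combinations are
deliberately skewed so that statistical learning can be probed through
trial-wise *Shannon surprise*, and feedback valence is reversed on a
scheduled 5/10/20 % of trials to calibrate difficulty.

`mslrl` implements the full computational pipeline around these designs
for simulation studies, model validation, and analysis of behavioural
data: task-structure generation, surprise computation, four
Rescorla–Wagner learning variants coupled to a Wiener diffusion choice
model, per-run maximum-likelihood fitting with BIC model selection,
parameter/model recovery harnesses, behavioural filtering and binning,
and export of trial-wise fMRI parametric-modulator regressors.

## The model

**Surprise.** The probability of the trial-*t* stimulus combination
*x<sub>t</sub>* is its Laplace-smoothed relative frequency,

> p(x_t) = (1 + Σ_{i&lt;t} [x_i = x_t]) / (n + t),

with *n* nominal combinations (9 pairs in match recognition, 16 in the
discriminative choice triplet variant, 4 in its non-matching-pair
variant), so p(x_0) = 1/n; surprise is I_t = −ln p(x_t) (nats).

**Learning.** Association values start at V = 0.5 and are updated by the
delta rule V ← V + η (R − V) with binary feedback R. The four variants
are: *simple* (chosen/presented pair only), *simple asymmetric* (separate
η⁺/η⁻ after positive/negative feedback), *transfer* (the other presented
pair moves toward the complement 1 − R; in match recognition, after
positive feedback all pairs sharing a stimulus with the presented pair
move toward 0), and *transfer asymmetric*.

**Choice.** The trial drift rate is
v_t = (V̄<sup>C</sup> − V̄<sup>O</sup>) · v_mod (discriminative choice,
after odds-ratio normalisation V̄ = V<sup>C</sup>(1−V<sup>O</sup>) /
[V<sup>C</sup>(1−V<sup>O</sup>) + V<sup>O</sup>(1−V<sup>C</sup>)]) or
v_t = (2V − 1) · v_mod (match recognition). Choices and reaction times
follow a Wiener diffusion with boundary separation *a*, non-decision time
τ, and starting point fixed at z = 0.5; the likelihood of each response
is the Wiener first-passage-time (WFPT) density

> f(t | v, a, z) = (π/a²) exp(−v a z − v² t/2) Σ_k k exp(−k²π²t/(2a²)) sin(kπz),

evaluated with an adaptive small-/large-time series switch. Per run,
the free parameters (learning rate(s), v_mod, a, τ) are estimated by
seeded multi-start maximum likelihood and the variant is selected by
BIC = k ln N − 2 ln L̂.

## Worked example

```r
library(mslrl)

cfg <- task_config("match_recognition", modality = "audio_visual", group = "child")
seq <- design_run(cfg, seed = 42)        # 42 trials, Table-like pairing counts
head(surprise_trace(seq), 4)
#>   trial key          p surprise
#> 1     0 A.1 0.11111111 2.197225     # first trial: ln 9
#> 2     1 B.2 0.10000000 2.302585
#> 3     2 A.0 0.09090909 2.397895
#> 4     3 C.2 0.08333333 2.484907

beh <- simulate_run(seq, rl_params("simple", eta_c = 0.38),
                    ddm_params(vmod = 2, a = 2.48, tau = 0.9), seed = 7)
fm <- fit_models(seq, beh, models = c("simple", "transfer"),
                 n_restarts = 4, seed = 1)
fm$fits[[fm$best]]
#> <msl_fit> simple  logL = -40.47  BIC = 95.69  N = 40
#>  eta_c   vmod      a    tau
#> 0.4418 2.2180 2.5517 0.9403
round(fm$bic, 2)
#>   simple transfer
#>    95.69    99.18

tr <- run_model(seq, beh, fm$fits[[fm$best]]$rl, fm$fits[[fm$best]]$ddm)
bin_summaries(seq, beh, tr)
#>   bin n_trials  accuracy  mean_rt mean_abs_drift
#> 1   1       13 0.6153846 2.242375      0.5199492
#> 2   2       13 0.9230769 1.787083      1.1141397
#> 3   3       14 0.9285714 1.745308      1.6165133
```

The generating parameters (η = 0.38, v_mod = 2, a = 2.48, τ = 0.9) are
recovered within single-run noise, the generating *simple* variant wins
the BIC comparison, and the learning curve shows the expected
accuracy rise and reaction-time drop across run thirds.

`run_pipeline(config, seed, out_dir)` chains
design → simulate → surprise → fit → select → analyse → regressor export
for a whole synthetic cohort and writes per-run TSV/JSON artefacts plus a
reproducibility manifest.

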