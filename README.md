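# itercue

Iterative Bayesian observer models for magnitude reproduction with symbolic
pre-cues.

## What this is for

In magnitude reproduction tasks — here, reproducing a traveled distance from
memory — responses regress toward the center of the recently experienced
stimulus range. This central-tendency bias is well explained by an iterative
Bayesian observer that fuses a noisy sensory measurement of each sample with
a prior learned trial by trial. `itercue` extends that account to designs
with a *symbolic* pre-cue: before each trial the observer is told the
upcoming sample will be "short" or "long", with no metric content, so the
meaning of the cue has to be learned during the experiment.

The package is for computational cognitive scientists who want to simulate,
fit, and compare two structurally different accounts of that learning on the
classic three-condition distance production-reproduction design (blocked
ranges without cue, interleaved ranges without cue, interleaved ranges with
cue; 110 trials each over sample distances 5–19 m with overlapping 11/13 m
probes).

## The models

All models operate on a log scale (`s = ln(d/d0) + noise`) and respond via
`d_r = exp(x_est + Δx)·d0`, where the shift term Δx encodes the loss
function. Every learned quantity is updated by a scalar Kalman filter for a
random-walk state, whose gain converges to the steady state `k*` with
`q/r = k*²/(1−k*)`; fitted noise ratios are reported as steady-state weights.

* **Basic** (no cue): `E[T|s] = w_m·s + (1−w_m)·μ_T`, with a single learned
  prior mean μ_T. Parameters: `w_m`, `Δx`.
* **Categorical**: the cue names one of two learned distance categories
  (means μ_a1, μ_a2) with reliability `p_C`;
  `E[T|s,c_j] = w_m·s + (1−w_m)·Σ_i P(a_i|s,c_j)·μ_ai`, where the category
  posterior combines cue mass `{p_C, 1−p_C}` with measurement evidence
  `S|A ~ N(μ_A, σ_S²+σ_A²)`. Only the cued category is updated. Parameters:
  `p_C`, `w_m`, `Δx`.
* **Cue-combination**: the cue is a second noisy channel with a learned
  mapped value `c_mp` per label plus a global prior;
  `E[T|s,c_mp] = (1−w_fu)·μ_T + w_fu·[(1−w_m)·c_mp + w_m·s]`. Prior and cued
  mapping are both updated each trial. Parameters: `w_m`, `w_fu`, `Δx`.

The two cued models coincide exactly when `p_C = 1` and `w_fu = 1`.

Around the models the package provides the trial-sequence generator for the
three conditions, a synthetic-subject/cohort simulator, least-squares fitting
(Levenberg–Marquardt, multi-start, Jacobian-based 95% CIs, R²), paired
signed-rank model comparison (exact with ties for small cohorts), and the
behavioral summaries (per-distance errors, range splitting,
overlapping-samples comparison, condition differences).

## Worked example

```r
library(itercue)

sq   <- generate_condition_sequence("IR-C", seed = 1)
pars <- categorical_params(p_c = 0.74, rho = gain_to_rho(0.33), delta_x = -0.04)

obs <- run_sequence(pars, sq)         # deterministic model prediction
overlapping_samples_comparison(obs)
#>   sample_distance_m mean_short_m mean_long_m difference_m
#> 1                11         9.80        11.4        1.60
#> 2                13        12.8         13.1        0.369

fit <- fit_observer("categorical", sq, obs)
fit
#> <observer_fit> categorical model, 100 trials
#>           p_c  w_m delta_x
#> estimate 0.74 0.33   -0.04
#> R-squared: 1  SS: 1.244e-26  converged: TRUE
```

The positive differences show the cue effect: 11 m and 13 m samples cued
"long" are reproduced longer than physically identical samples cued "short",
because the estimate is shrunk toward the learned mean of the cued category.
The refit recovers the generating parameters exactly from the model's own
noise-free output. With a noisy 20-subject cohort the group-mean fit remains
close but is no longer exact, e.g.:

```r
coh <- simulate_cohort(20, pars, sq, noise_sd = 0.15, seed = 42)
fit_observer("categorical", sq, group_mean_responses(coh))
#>             p_c    w_m delta_x
#> estimate 0.6707 0.4056 -0.0446
#> lower    0.6069 0.3655 -0.0520
#> upper    0.7344 0.4457 -0.0371
#> R-squared: 0.9775  SS: 18.46  converged: TRUE
```

`run_study()` composes the whole pipeline (all three conditions, cohorts,
per-subject and group fits of all applicable models, model comparison, and
summary tables) from a single seeded `study_config()`. A thin command-line
front-end over the same functions is installed at
`inst/scripts/itercue` (subcommands `design`, `simulate`, `fit`, `analyze`,
`run-study`).

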