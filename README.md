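# augbin — augmented binary analysis of composite responder endpoints

Composite responder endpoints declare a patient a responder when a
continuous score (e.g. an ACR-N percent improvement) reaches a cut-off
*c* **and** no binary failure — rescue medication, protocol-restricted
treatment, withdrawal — occurred. The usual analysis dichotomises the
score and fits a logistic regression on the resulting flag, which wastes
the continuous information; in small trials (rare diseases, early phase),
that waste is the difference between detecting a treatment and not.

`augbin` implements the **augmented binary method**: a factorized joint
model

    f(y1, y2 | z) · Pr(D1 = 0 | z) · Pr(D2 = 0 | z, y1)

of the interim/final scores `(y1, y2)` (bivariate normal; fitted by GLS
maximum likelihood or GEE) and the interval failure indicators `D1, D2`
(logistic). Per-patient response probabilities under each assignment

    p̃(z) = Pr(D1=0|z) ∫ (1 − π_D2(z, y1)) Φ((μ₂|₁(y1) − c)/σ₂|₁) φ(y1) dy1

are evaluated by Gauss–Hermite quadrature, averaged over all randomized
patients, and turned into treatment effects on the log-odds,
risk-difference and log-risk-ratio scales with delta-method confidence
intervals. Because the component models are vulnerable at small n, the
package includes two small-sample corrections:

* **Firth penalized likelihood** for every logistic component
  (finite estimates under perfect separation; shrinkage + smaller
  variance);
* the **Morel–Bokossa–Neerchal** inflation `f·A + δ·ξ·B` of the GEE
  sandwich covariance.

The standard binary comparator, a calibratable synthetic-trial
generator, re-sampling/permutation harnesses, and an
operating-characteristics engine (power, type I error, coverage, CI
width, separation frequency over n = 30…80) round out the toolkit.

## Worked example

```r
library(augbin)

cfg   <- read_analysis_config(
  system.file("extdata", "config_reference.yaml", package = "augbin"))
trial <- read_trial_csv(
  system.file("extdata", "synthetic_trial_n80.csv", package = "augbin"),
  config = cfg)

fit <- fit_augmented_binary(trial, cfg)
estimate_effect(fit, trial, scale = "log_odds")
#> <effect_estimate> log_odds (augmented_binary)
#>   estimate 0.6278 (SE 0.3550), 95% CI [-0.0679, 1.3236]
#>   arm-average response probabilities: treated 0.5313, control 0.3769

bin <- fit_standard_binary(trial, cfg)
estimate_effect_binary(bin, trial, scale = "log_odds")
#> <effect_estimate> log_odds (standard_binary)
#>   estimate 0.5896 (SE 0.4521), 95% CI [-0.2965, 1.4757]
#>   arm-average response probabilities: treated 0.5732, control 0.4268
```

Both methods estimate a similar log-odds effect (~0.6) on this bundled
80-patient synthetic trial, but the augmented binary interval is ~21%
narrower (1.39 vs 1.77) — the efficiency gain from modelling the score
instead of its dichotomisation. Under the 1/√n width scaling, a width
reduction `w` is worth a `1 − (1 − w)²` reduction in required sample
size (`ci_width_to_sample_size_reduction()`).

Simulation engine:

```r
oc <- run_operating_characteristics(
  list(oc_method("binary", adjusted = TRUE),
       oc_method("augbin", "GLS", adjusted = TRUE)),
  reference_alternative(),       # calibrated: response 0.470 vs 0.336
  n_grid = seq(30, 80, 10), n_reps = 1000, mode = "power", seed = 1)
build_comparison(oc, oc, "binary_adjusted", "augbin_gls_adjusted")
```

A command-line front end lives in `inst/cli/augbin.R`
(`fit`, `simulate`, `oc` subcommands).

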