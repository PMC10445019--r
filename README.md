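# stridedep

Variability and serial dependence of human leg stiffness across running
strides — and what that dependence does to the statistics built on top of
per-stride measurements.

## The scientific problem

Treadmill running studies compute biomechanical parameters (here: leg
stiffness) once per stride and then average, test and model them as if
strides were independent. If the per-stride series Y₁, …, Yₙ is serially
correlated, the iid variance formula Var[Ȳ] = σ²/n is wrong by the factor

    R(ρ₁, …, ρₖ) = 1 + 2 Σₖ (1 − k/n) ρₖ ,

so confidence intervals can be several-fold too narrow (positive
correlation, R > 1) or too wide (negative, R < 1). `stridedep` provides,
for researchers in biomechanics and locomotor time-series analysis:

- **Pre-processing** of treadmill trials: 300 Hz vertical ground reaction
  force paired with 150 Hz pelvis markers, stance segmentation by
  F_y > 0, centre-of-mass extraction from six pelvis markers, and
  recentring from the treadmill frame to the world frame (x′ = x + v·t).
- **Two per-stride leg-stiffness estimators**: `k_max` (peak force over
  leg compression ΔL, with the horizontal-sweep geometric correction) and
  `k_ols` (no-intercept least squares of the weight-added force on the
  spring-mass predictor y·(l₀/√(x² + y²) − 1)), plus a validation variant
  without the weight term.
- **Stride-independence tests**: per-lag Yule test
  (|ρ̂(k)| > z_{α/2}/√n), Ljung-Box portmanteau test (default max lag 40),
  Bonferroni adjustment across subjects, and a Grubbs screen for
  first-stride outliers.
- **Variance correction** via the ratio R above (constant-ρ, single-lag
  and from-ACF constructors).
- **Cohort models**: random-intercept linear mixed-effects models
  k_ij = β₀ᵢ + β₁·S_ij (+ β₂·v_ij) + ε_ij fitted by REML with
  Satterthwaite degrees of freedom, and follow-up regressions of
  Ljung-Box p-values on age and mass.
- A **synthetic-data generator**: a planar spring-loaded inverted pendulum
  (SLIP) gait simulator driven by a latent autoregressive per-stride
  stiffness process, with exact ground truth (injected stiffness, stance
  intervals, pre-noise CoM), so the whole pipeline is testable without any
  external dataset.

See `vignettes/stride-dependence.Rmd` for the model, the design decisions
and the validation strategy.

## Worked example

Simulate a 4-subject cohort (60 strides per trial at 2.5/3.5/4.5 m s⁻¹,
AR(1) stiffness with φ = 0.6), run the analysis, and summarise:

```r
library(stridedep)
sim <- file.path(tempdir(), "sim"); out <- file.path(tempdir(), "out")
run_simulate(sim, n_subjects = 4, n_strides = 60,
             velocities = c(2.5, 3.5, 4.5), seed = 1)
res <- run_analyze(file.path(sim, "manifest.json"), out,
                   methods = c("kmax", "kols"),
                   threshold = 10, min_samples = 10)
head(res$cohort)
```

```
  subject_id velocity method n_strides      lb_p max_significant_lag      R lb_reject_bonferroni
1        S01      2.5   kmax        60 6.219e-01                  37 0.7962                FALSE
2        S01      2.5   kols        60 6.482e-03                  37 1.8083                 TRUE
3        S01      3.5   kmax        60 5.020e-01                   2 2.4767                FALSE
4        S01      3.5   kols        60 2.345e-03                   3 3.5091                 TRUE
5        S01      4.5   kmax        60 5.308e-12                  30 2.3811                 TRUE
6        S01      4.5   kols        60 5.950e-19                  31 1.2669                 TRUE
```

One row per (subject, velocity, estimator): `lb_p` is the Ljung-Box
p-value at max lag 40 (`lb_reject_bonferroni` applies α/N across the
cohort's subjects), `max_significant_lag` the largest Yule-flagged lag,
and `R` the variance-to-variance ratio built from the Yule-significant
lags — e.g. row 4 says the iid formula would understate the variance of
this subject's mean stiffness 3.5-fold. The injected AR(1) dependence is
detected for most series; the noisier `k_max` estimator (see the vignette
on its boundary-sampling jitter) dilutes the evidence at lower speeds.

The variance-ratio calculator is also usable stand-alone:

```r
variance_ratio_constant(0.05, n = 101)$R          # 6      — iid CI 6x too narrow
variance_ratio_single(0.2408617, lag = 14, n = 75)$R  # 1.391802
```

`run_report(out, "report/")` adds CSV summary tables (and optional
figures): per-subject max-lag bars, Ljung-Box p-values against the α
line, p-value-vs-age/mass regressions, closed-form R sweeps, and the
mixed-model coefficient table (estimate, s.e., Satterthwaite d.f., t, p
per fixed effect).

A thin command-line front end wraps the same functions:

```sh
Rscript inst/cli/stridedep.R simulate --out sim --subjects 4 --strides 60 --seed 1
Rscript inst/cli/stridedep.R analyze  --manifest sim/manifest.json --out out \
        --method kmax,kols --threshold 10 --min-samples 10
Rscript inst/cli/stridedep.R report   --analysis out --out report --figures
```

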