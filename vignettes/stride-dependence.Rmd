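---
title: "Quantifying stride-to-stride dependence of leg stiffness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying stride-to-stride dependence of leg stiffness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stridedep)
```

## The problem

Locomotion studies routinely compute a biomechanical parameter — here, leg
stiffness during treadmill running — once per stride and then summarise the
per-stride series as if the strides were independent draws. If consecutive
strides are serially correlated, the familiar variance formula for a sample
mean, $\sigma^2/n$, is wrong, and every downstream confidence interval and
test inherits the error. `stridedep` implements the full chain needed to
examine this question on running data, and a physics-based synthetic-data
generator so that every stage can be validated against known ground truth.

The pipeline is:

1. **Segmentation** — split a trial (pelvis marker trajectories at 150 Hz,
   vertical ground reaction force at 300 Hz) into stance phases where
   $F_y > 0$.
2. **Stiffness estimation** — one leg-stiffness value per stride, by two
   estimators.
3. **Dependence testing** — per-lag Yule test on the sample
   autocorrelation function (ACF), Ljung-Box portmanteau test, Bonferroni
   adjustment across subjects, and a Grubbs screen for first-stride
   outliers.
4. **Variance correction** — the variance-to-variance ratio $R$
   quantifying the error made by the iid formula.
5. **Cohort models** — random-intercept linear mixed-effects models of
   stiffness on stride number and treadmill speed, and follow-up
   regressions of Ljung-Box p-values on age and mass.

## The synthetic-data generator

The generator is a planar spring-loaded inverted pendulum (SLIP): a point
mass of mass $m$ on a massless linear leg spring with rest length $l_0$
(the standing centre-of-mass height) and per-stride stiffness $k_i$. During
stance the foot is pinned and the equations of motion are

$$m\ddot{\mathbf{r}} = k\,(l_0 - L)\,\frac{\mathbf{r}}{L} - m g\,\hat{y},
\qquad L = \lVert \mathbf{r} \rVert,$$

with $\mathbf{r}$ the CoM position relative to the foot. The vertical ground
reaction force is exactly $F_y = k (l_0 - L)\, y / L$, zero at touchdown and
takeoff ($L = l_0$) and zero throughout flight. The dynamics are integrated
with fixed-step RK4 at $dt = 10^{-4}$ s; because the stance dynamics are
conservative, the integration accuracy is directly checkable — the relative
energy drift over a stance is below $10^{-12}$ at the default step, far
inside the $10^{-6}$ bound the test suite enforces. Takeoff ($L \ge l_0$
after compression) is located by bisection on the step size to $10^{-9}$ s.

Three deliberate design choices:

* **Per-stride apex reset.** Every stance is re-initialised from the nominal
  ballistic apex. A free-running passive SLIP drifts or falls after a few
  strides for generic parameters; resetting guarantees arbitrarily long
  sequences and — more importantly — makes the injected stiffness process
  the *only* channel of cross-stride dependence. Ground truth for the
  dependence tests is therefore exact by construction.
* **Latent AR stiffness.** Per-stride stiffness follows
  $k_i = \bar{k} + z_i$ with $z_i$ a stationary autoregressive process
  (AR(1) with coefficient $\varphi$ in all shipped defaults, for which
  $\rho_k = \varphi^k$), drawn via `stats::arima.sim` (stationarity enforced
  at construction, burn-in discarded by the library). Draws below
  $0.1\,\bar{k}$ are clipped (and counted) to keep every value a physically
  usable stiffness.
* **Markers as CoM plus offsets.** The six pelvis markers (left/right
  anterior superior iliac spine, posterior iliac spine, iliac crest) are
  emitted as the CoM plus fixed sagittal offsets that sum to zero per
  coordinate, so the six-marker average recovers the CoM exactly on
  noiseless data. Coordinates are written in the treadmill frame
  ($x_{\text{tread}} = x_{\text{world}} - v t$); Gaussian measurement noise
  (defaults: 1 mm marker, 5 N force — plausible magnitudes for optical
  capture and instrumented treadmills, configurable) is added last, after
  the ground truth is recorded.

What the generator does **not** emulate: joint-level and 3-D dynamics,
soft-tissue artefact, surface compliance, left/right asymmetry, fatigue
drift, or treadmill-speed fluctuation. Passing tests on synthetic data
therefore validate the *statistical machinery* and the *estimator
algebra* — they do not certify the biomechanical fidelity of any particular
stiffness estimate on real recordings.

Default study conditions mirror the treadmill protocol the package
targets: velocities $\{2.5, 3.5, 4.5\}$ m s$^{-1}$, 150/300 Hz clocks with
force sample $2i$ simultaneous with marker frame $i$, mean stiffness
20 kN m$^{-1}$ with 1 kN m$^{-1}$ innovations, adult cohorts (ages 20–45,
masses 55–90 kg, $l_0$ 0.90–1.05 m).

## Segmentation choices

* **Stance definition.** Maximal runs of $F_y >$ threshold on the 150 Hz
  clock (forces first downsampled by keeping every other sample). The
  threshold default is 0 N — the literal definition; for noisy force
  channels a threshold of about twice the noise sd plus a minimum run
  length (`min_samples`) suppresses spurious flight-phase crossings. With
  the shipped noise defaults, threshold 10 N and `min_samples` 10 recover
  every true stance with boundaries within one sample.
* **Recentring.** The belt displacement is added back to the horizontal
  coordinate only: $x' = x + vt$, $y' = y$. A mode that also ramps $y$ by
  $vt$ exists (`"verbatim"`) for audit purposes, but a vertical belt ramp
  of ~0.6 m per stance has no physical interpretation for treadmill
  running and distorts every stiffness estimate; it is not the default.
* **Boundary strides.** Stance runs touching the first or last sample of a
  trial are partial and always excluded. Complete first and last strides
  are *kept* by default: removing them discards real information unless an
  outlier test justifies it — that is what the Grubbs screen is for.
  Optional trimming (`trim = TRUE`) is available and logged.
* **Indexing.** 0-based, half-open sample intervals everywhere.

## The two stiffness estimators

**Peak-force / compression** (`k_max`): $k = F_{\text{leg}} / \Delta L$ with

$$\Delta L = \max(y) - \min(y) + l_0\left(1 - \sqrt{1 -
\left(\frac{\max(x) - \min(x)}{2 l_0}\right)^2}\,\right),$$

and $F_{\text{leg}}$ the vertical force at the sample of minimum CoM height,
corrected for body weight. Whether that correction subtracts or adds $mg$
is ambiguous in parts of the literature; the package defaults to
subtraction and records the convention (`"subtract"`, `"add"`, `"none"`) in
its outputs.

**No-intercept least squares** (`k_ols`): the slope of
$F_y + mg$ on the spring-mass predictor
$p_t = y_t\,(l_0/\sqrt{x_t^2 + y_t^2} - 1)$, i.e.
$\hat{k} = \sum p_t r_t / \sum p_t^2$, fitted per stance. A validation
variant (`k_ols_noweight`) regresses the raw $F_y$; on noiseless SLIP data
the force law is exactly $F_y = k\,p_t$, so this variant must recover the
injected stiffness — the package's strongest end-to-end correctness check
(it does, to $<10^{-8}$ relative).

**The foot-position nuisance.** The predictor's $x$ must be measured from
the planted foot, which pelvis kinematics do not observe. Fixed conventions
(foot below the CoM at minimum height, or at the midpoint of the x sweep)
are exact only for symmetric stance orbits and biased ~10% on the
asymmetric orbits the SLIP model actually produces. The default therefore
treats the foot $x$ as a nuisance parameter and profiles it out of the
least-squares fit (1-D minimisation of the profiled residual sum of squares
over the CoM's x sweep). The fixed conventions remain available as options.

**Known limitation of `k_max`.** $\Delta L$ depends on the extreme $y$ and
$x$ values of the stance, which are attained at the boundary samples; their
timing jitters by up to half a sample (±3.3 ms at 150 Hz) from stride to
stride, injecting ~5% noise into $\Delta L$ — the same order as typical
stride-to-stride stiffness variation. Consequently the rank correlation
between injected and estimated stiffness saturates near 0.85 for `k_max`
even on noiseless data, versus >0.999 for the least-squares estimators.
This is a property of the estimator at 150 Hz, not of the implementation.
Crucially, serial-dependence conclusions are unaffected in either case: the
sample ACF is invariant under affine transformations of the series, so an
approximately affine estimator bias leaves the dependence structure intact
(a property the test suite checks directly).

## Dependence testing

The sample ACF uses the standard biased-denominator estimator
$\hat\gamma(h) = n^{-1}\sum_{t=1}^{n-h}(X_t - \bar X)(X_{t+h} - \bar X)$,
$\hat\rho(h) = \hat\gamma(h)/\hat\gamma(0)$, with the full-series mean in
both factors.

* **Yule test.** Under the iid null $\sqrt{n}\,\hat\rho(h)$ is
  asymptotically standard normal, so lag $h$ is flagged iff
  $|\hat\rho(h)| > z_{\alpha/2}/\sqrt{n}$. No adjustment is applied across
  lags within one series — the multiplicity correction in the pipeline is
  applied across *subjects* (Bonferroni, $\alpha/N$), matching how such
  cohorts are analysed.
* **Ljung-Box.** $Q = n(n+2)\sum_{h=1}^{m}\hat\rho(h)^2/(n-h)$ against
  $\chi^2_m$, with $m = 40$ by default (capped at $n - 1$ for short
  series). Chi-square tails come from `stats::pchisq`.
* **Variance-to-variance ratio.**
  $R = 1 + 2\sum_{h}(1 - h/n)\,\rho_h$, so that
  $\mathrm{Var}[\bar Y] = (\sigma^2/n)\,R$ for a stationary series.
  Constant-$\rho$ ($R = 1 + \rho(n-1)$), single-lag, and from-ACF
  constructors are provided; the from-ACF default sums only
  Yule-significant lags (an all-lags mode exists, and the mode used is
  recorded in every output).
* **Grubbs screen.** Two-sided single-outlier test with the t-based
  critical value; iterative re-testing exists but is off by default because
  repeated testing on short series overcounts outliers.

Monte-Carlo calibration (checked in the test suite at fixed seeds): with
iid Gaussian input at $n = 200$ over 2000 replicates, the Ljung-Box size at
$\alpha = 0.05$, $m = 10$ falls in $[0.035, 0.07]$ and the per-lag Yule
size at lags 1–5 within $0.05 \pm 0.015$; under AR(1) $\varphi = 0.6$ at
$n = 80$ the Ljung-Box power exceeds 95%.

## Cohort models

`fit_lmem` fits $k_{ij} = \beta_{0i} + \beta_1 S_{ij} (+ \beta_2 v_{ij}) +
\varepsilon_{ij}$ with a random intercept per subject, by REML via
`lmerTest`, reporting Satterthwaite degrees of freedom (the fractional
d.f. convention used for such cohort tables). Random slopes are
deliberately excluded — at cohort sizes of a few dozen subjects they are
unstable. Stride number enters raw (uncentred, 0-based); a singular fit
(zero intercept variance) is flagged, not raised, and in that limit the
fixed effects provably equal pooled OLS (checked numerically). The
follow-up `regress_pvalue_on_covariate` is a deliberately minimal
univariate OLS of one Ljung-Box p-value per subject on age or mass.

## Numerical and degenerate-input policy

* Constant series: ACF, Ljung-Box and Grubbs raise explicit degenerate
  errors rather than returning NaN.
* Zero compression or an identically-zero predictor: undefined-stiffness
  errors; `stiffness_series` drops such strides with a logged gap instead
  of failing the trial.
* Stationarity of the AR specification is rejected at construction
  (roots of the AR polynomial strictly outside the unit circle).
* Ties in $\arg\min y$: first index wins.
* All randomness descends from one integer master seed through
  documented fixed substreams (`derive_seed`), so cohort simulation is
  bit-reproducible file-for-file.

## Problem sizes used in validation

The shipped validation suite runs at: 2000 replicates for size
calibration ($n = 200$), 1000 for power ($n = 80$), a 200-stride SLIP
trial for end-to-end ACF recovery, 20-stride trials for segmentation
fidelity, and a 28-subject × 3-velocity × 80-stride simulated cohort for
mixed-model recovery — sizes chosen to match the study conditions the
package emulates while keeping the full suite around ten seconds on a
laptop-class machine.

## A worked miniature

```{r example, eval = FALSE}
sim_dir <- file.path(tempdir(), "sim")
out_dir <- file.path(tempdir(), "out")
run_simulate(sim_dir, n_subjects = 4, n_strides = 50,
             velocities = c(2.5, 3.5, 4.5), seed = 1)
res <- run_analyze(file.path(sim_dir, "manifest.json"), out_dir,
                   methods = c("kmax", "kols"),
                   threshold = 10, min_samples = 10)
head(res$cohort)
run_report(out_dir, file.path(tempdir(), "report"))
```

Each cohort row carries the Ljung-Box p-value and its Bonferroni decision,
the largest Yule-significant lag, and the variance ratio $R$ for one
(subject, velocity, method) series; the report step adds the closed-form
$R$ sweeps and the mixed-model coefficient table.
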