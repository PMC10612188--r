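---
title: "Modelling HbA1c variability, glycemic-control targets, and outcome risk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling HbA1c variability, glycemic-control targets, and outcome risk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The scientific problem

Long-term glycated haemoglobin (HbA1c) carries two distinct signals for a
patient with type 2 diabetes: its *level* (mean over follow-up) and its
*variability* from visit to visit. Large glucose-lowering trials have shown
that the benefit or harm of intensive glycemic control can differ sharply
between patients, and visit-to-visit HbA1c variability is a candidate
effect modifier: patients with stable HbA1c may benefit from tight control
while patients with erratic HbA1c may be harmed by it. **glycvar**
implements a complete, testable pipeline for this analysis:

1. per-patient variability metrics from a longitudinal visit table,
2. unsupervised grouping of patients into low / medium / high variability,
3. survival modelling of treatment effects within the groups, including
   interaction and trend tests,
4. threshold (two-piecewise) and smooth dose-response analyses of mean
   HbA1c against each outcome, and
5. a synthetic cohort generator with known ground truth, so that every
   stage has a recoverable target.

# Variability metrics

For a patient with HbA1c measurements $v_1, \dots, v_n$ ordered by time:

* **HVS** (HbA1c variability score) is the percentage of successive changes
  exceeding 0.5 percentage points:
  $\mathrm{HVS} = 100 \cdot \#\{i : |v_{i+1} - v_i| > 0.5\} / (n-1)$.
  The inequality is strict; an exact change of 0.5 does not count. The
  denominator is the number of *changes* ($n-1$), because a change requires
  a pair of measurements; a `denominator = "measures"` switch divides by
  $n$ instead, since both conventions appear in the applied literature.
  Patients with fewer than 2 measurements have no HVS and are excluded by
  the pipeline's eligibility stage (with a logged reason).
* **SD** is the ordinary sample standard deviation ($n-1$ denominator,
  with a switch for $n$).
* **mean HbA1c** is the arithmetic mean of all visit values, baseline
  included.
* **VIM** (variation independent of the mean) rescales the SD as
  $\mathrm{VIM}_i = \bar{M}^{x} \cdot \mathrm{SD}_i / m_i^{x}$, where $m_i$
  is the patient mean, $\bar M$ the population mean, and the exponent $x$
  is the OLS slope of $\log \mathrm{SD}_i$ on $\log m_i$ across patients.
  By construction VIM is (nearly) uncorrelated with the mean — its defining
  property, asserted in the test suite — whereas the raw SD is materially
  correlated with it. Patients with $\mathrm{SD} = 0$ are excluded from the
  exponent fit (the log is undefined) and counted.

Duplicate visit timestamps are an error rather than being silently
averaged: they indicate an upstream data problem.

# Variability grouping

Patients are clustered in (HVS, SD) space — or (HVS, VIM) in the
sensitivity variant — by three methods: **K-means** (Lloyd's algorithm,
squared-Euclidean objective), **K-medians** (L1 assignment,
coordinate-wise median updates), and **quantile tertiles** on a single
metric. Design choices, each of which was genuinely open:

* **Standardization.** HVS spans 0–100 while SD spans roughly 0–2;
  unscaled K-means would ignore SD entirely. Features are z-scored by
  default (`scale = "zscore"`), with the scaling stored so new data can be
  assigned reproducibly. A `"none"` option preserves raw-space clustering.
* **Initialization.** k-means++-style seeding with `n_init = 20` restarts,
  keeping the best objective; a fixed seed makes the fit deterministic.
* **Empty-cluster repair.** An empty cluster is re-seeded at the point
  farthest from its assigned centroid.
* **Ties.** Nearest-centroid ties go to the lowest centroid index;
  quantile ties are resolved so that patients with identical metric values
  always share a group (the group of the first tied member in stable
  order), so total ties collapse to one group with a warning.
* **Convergence.** Exact assignment fixpoint or 300 iterations; the
  objective trace is recorded and is non-increasing (asserted in tests).

Cluster quality is scored by three internal validation indices implemented
from first principles (and checked against naive $O(n^2)$ oracles):
Calinski–Harabasz (higher better), Davies–Bouldin (lower better), and
silhouette (higher better; a singleton's silhouette is defined as 0).
`select_k()` scans $k = 2..9$ and picks the $k$ maximizing the mean rank
of (silhouette, −Davies–Bouldin); the exact rule for combining the two
indices is a declared convention, and the full score table is always
reported so other rules can be applied post hoc. For the grouped analyses
$k = 3$ is fixed, and the three clusters are ordered into low / medium /
high by their within-cluster mean HVS.

# Survival modelling

All time-to-event modelling uses the **Weibull accelerated failure time
(AFT) model**, fitted by the package's own maximum-likelihood routine:
$\log T = X\beta + \sigma W$ with $W$ standard minimum-Gumbel and right
censoring. The AFT family is used deliberately: it remains valid for
hazard-ratio summaries when proportional hazards is doubtful, and AIC/BIC
(whose identities $\mathrm{AIC} = 2p - 2\ell$,
$\mathrm{BIC} = p\log n - 2\ell$ are asserted exactly) allow model
comparison. Numerics:

* Newton–Raphson on $(\beta, \log\sigma)$ with analytic gradient and
  Hessian (implemented in C++), ridge damping and step halving; a
  quasi-Newton (BFGS) restart is used if Newton stalls. The start is
  data-driven (intercept at the median log time, $\sigma = 1$) and the fit
  is deterministic.
* The gradient convergence tolerance scales with $|\ell|$ (itself $O(n)$),
  mirroring the relative criteria of standard survival fitters.
* The covariance is the inverse observed information; if the information
  matrix is singular (e.g. more parameters than events can support), the
  fit is flagged and downstream conversions refuse it rather than
  reporting unstable intervals.
* Under Weibull errors the AFT model is also proportional-hazards, with
  $\mathrm{HR} = \exp(-\beta/\sigma)$ per unit covariate. Confidence
  intervals use the delta method on $(\beta, \log\sigma)$. The test suite
  cross-checks the entire fit against `survival::survreg` and checks the
  HR against a person-years rate ratio in the exponential case.

`stratified_treatment_hr()` fits a covariate-adjusted model per
variability group and reports the treatment HR for each; interaction is
tested by a likelihood-ratio test between pooled models with and without
treatment-by-group terms (df = 2), and a dose-response trend by a Wald
test on a single treatment-by-ordinal-group (0/1/2) column. The ordinal
coding of the trend test is a convention; the interaction LRT is the
primary test.

# Threshold (two-piecewise) analysis

The relation between mean HbA1c and the log hazard is modelled as a
continuous hinge: $\beta_1 \min(x, K) + \beta_2 \max(x - K, 0)$. The
breakpoint $K$ is estimated by profile likelihood over a fixed grid
(default: the 5th–95th exposure percentiles in 0.01% steps; ties go to the
smallest candidate), which is reproducible and matches common two-piecewise
practice. Both slopes are reported as per-1% hazard ratios; segments with
fewer than 30 events are flagged as sparse rather than suppressed. The
grid is trimmed to the central percentiles to avoid boundary instability.

* **Curvature test.** The one-line model is compared with the two-piece
  model at $\hat K$ by an LRT with df = 1. Because $\hat K$ is data-driven
  this is mildly anti-conservative; the null-simulation bound in the test
  suite is set accordingly (rejection rate $\le 0.15$ at $\alpha = 0.05$).
* **Bootstrap CI.** Patients (not events) are resampled with replacement;
  the percentile 2.5/97.5 interval of $\hat K$ over `n_boot` resamples
  (default 500, minimum 200) is reported, deterministic given the seed.
  Searches inside resamples use a coarser grid (0.05% steps): the
  discretization is an order of magnitude below the interval width, and
  this keeps the bootstrap tractable. More than 20% failed resample fits
  is an error.

# Smooth dose-response curves

`fit_smooth_hr()` estimates the hazard ratio as a smooth function of a
continuous exposure by entering a natural cubic spline basis (df = 4 by
default, knots at exposure quantiles) into the AFT linear predictor — an
unpenalized modest-df smooth keeps the likelihood machinery unified with
the rest of the package, rather than introducing a separate penalized
smoother. The curve is anchored at HR = 1 at the reference exposure
(default: the median; the choice of reference shifts the curve but not its
shape), with pointwise delta-method bands. With df = 1 the curve reduces
exactly to the log-linear model's per-1% HR (asserted to 1e-6). The
curve grid spans the 2.5th–97.5th exposure percentiles, where the basis is
supported by data.

# The synthetic cohort generator

Real trial data of this kind are access-restricted, so the generator is a
first-class module: it emulates the *design* of a large
intensive-vs-standard glucose-lowering trial and plants known effects for
recovery testing.

* **Trajectories.** HbA1c starts at a patient-specific baseline
  (mean 8.3%, SD 1.1%) and decays exponentially (half-life 6 months)
  toward the arm target — 6.4% intensive, 7.5% standard, the achieved
  levels typical of such trials — plus stationary AR(1) shocks
  ($\rho = 0.3$) whose SD is set by a hidden volatility stratum. The
  three-stratum mixture (weights 0.45/0.39/0.16, shock SDs 0.3/0.6/1.0%)
  was chosen once to produce per-group SD-of-HbA1c means near 0.5/0.8/1.1%
  and HVS means separating near 19/45/75 — the magnitudes such cohorts
  report. The visit schedule (monthly-to-bimonthly in year 1, then every
  4 months to month 60) satisfies the at-least-4-visits-in-year-1 design;
  trial protocols rarely publish the later calendar, so the 4-monthly
  default is an assumption. Values are clipped to the physiologic (3, 20)%.
* **Outcomes.** Event times are Weibull proportional-hazards (shape 1.2)
  with per-year baseline rates set so that roughly 10% of patients have a
  MACE and 7% die over ~5 years. The log hazard adds (i) a piecewise-linear
  effect of the patient's *realized* mean HbA1c with stratum-specific
  breakpoints and slopes, (ii) a stratum-specific treatment effect — the
  generative encoding of the effect-modification hypothesis — and (iii)
  small covariate effects. Death truncates MACE follow-up; both outcomes
  share the administrative censor.
* **Censoring.** Administrative at 5 years plus a Uniform(3, 5)-year
  early-censoring draw per patient, giving a realistic follow-up
  distribution.
* **Randomness.** One master seed spawns per-patient, per-purpose
  substreams through a murmur3-style avalanche hash, so enlarging the
  cohort never perturbs existing patients and every run is bit-for-bit
  reproducible. (A linear seed mix is *not* sufficient here: R scrambles
  `set.seed` input only weakly, and linearly related stream seeds produce
  visibly correlated draws — discovered and fixed during development, and
  the reason the hash is part of the design.)

**What the generator does not emulate:** pharmacological detail (drug
classes, hypoglycemia event streams), informative censoring, correlated
covariates, measurement error in HbA1c, or visit-schedule irregularity
beyond the planted single-visit patients. Passing recovery tests therefore
demonstrates that the *statistical machinery* is correct under a
correctly specified data model, not that the paper-reported effect sizes
hold in any particular real cohort.

# The pipeline

`run_full_analysis()` sequences everything from one `run_config()`:
eligibility filtering (fewer than 2 HbA1c measures; optionally follow-up
< `min_followup_years` as a sensitivity analysis), metrics, clustering and
validation scans, a descriptive group summary, stratified treatment HRs
with interaction/trend tests, per-group threshold reports, smooth curves,
and a manifest (config hash, seeds, exclusion counts) sufficient to
reproduce the run. Group-level threshold cells whose fits are degenerate
(too few events for the adjustment set) are reported as empty rows rather
than aborting the run — the analogue of "not estimable" entries in applied
threshold tables — while a failure on the total cohort is a genuine error.

# Problem sizes used in validation

The test suite and the acceptance script run everything at desk scale,
with sizes chosen once as a compromise between statistical resolution and
runtime: metric oracles on 1,000 random trajectories; index oracles on 50
random datasets ($n \le 200$); exhaustive k-means enumeration on 100
trials ($k = 2$ at $n \le 12$, $k = 3$ at $n \le 9$, where $3^{n-1}$
labelings remain enumerable); AFT recovery at $n = 10{,}000$; interaction
detection over 25 replicates at $n = 12{,}000$ (and a 200-replicate null
at $n = 1{,}000$); threshold recovery over 25 replicates and bootstrap
coverage over 50 replicates at $n = 6{,}000$ with 200 resamples; smooth
curves at $n = 8{,}000$ (J-shape recovery judged on the median argmin of
five replicates, since a single draw is noisy against the tolerance); and
an end-to-end run at $n = 8{,}000$ plus a
bit-reproducibility run at $n = 1{,}000$. The acceptance script uses a
6,000-patient cohort. Event rates in the threshold simulations are set to
~13% so that the profiled kink is supported by several hundred events —
a design choice of the simulations, stated here once.

# Known limitations

* The HVS denominator question (changes vs measures) is genuinely
  ambiguous in the applied literature; both are implemented, and analyses
  should state which was used.
* The df = 1 curvature LRT ignores breakpoint selection, a deliberate
  convention of two-piecewise practice; its anti-conservatism is
  quantified in the test suite rather than corrected.
* Silhouette computation materializes the full distance matrix
  ($O(n^2)$ memory); at cohort sizes much beyond $10^4$ patients the
  validation scan should be run on a subsample.
* The generator's strata drive both volatility and treatment-effect
  modification; it cannot, by design, probe confounded settings where
  variability is a marker rather than a modifier.
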