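# glycvar

Tools for analysing long-term **HbA1c variability** in longitudinal
diabetes cohorts, and for asking the clinical question that motivates it:
*should a patient's glycemic-control target depend on how stable their
HbA1c is?*

In large intensive-vs-standard glucose-lowering trials, the benefit of
tight control differs across patients. Visit-to-visit HbA1c variability is
a candidate effect modifier: patients with stable HbA1c may benefit from
intensive treatment while patients with erratic HbA1c may be harmed by it,
and the mean-HbA1c level with the lowest risk may itself shift with the
variability level. **glycvar** implements the full analysis pipeline for
this question, end to end, with a synthetic cohort generator so every stage
has a recoverable ground truth.

## What it computes

* **Variability metrics** per patient from a long visit table:
  * HVS (HbA1c variability score):
    `100 · #{i : |v[i+1] − v[i]| > 0.5} / (n − 1)` — the percentage of
    successive changes exceeding 0.5 percentage points;
  * SD of HbA1c, mean HbA1c;
  * VIM (variation independent of the mean):
    `VIM_i = popmean^x · SD_i / mean_i^x`, with `x` fitted by OLS of
    `log SD` on `log mean` so VIM is uncorrelated with the mean.
* **Variability grouping**: own implementations of K-means (Lloyd +
  k-means++ restarts), K-medians (L1), and quantile tertiles, scored by
  first-principles Calinski–Harabasz, Davies–Bouldin and silhouette
  indices with a k = 2..9 selection scan; k = 3 clusters are ordered
  low / medium / high by mean HVS.
* **Weibull accelerated failure time (AFT) survival models**, fitted by
  the package's own Newton maximum-likelihood routine (C++ core):
  `log T = Xβ + σW`, hazard ratios via the Weibull identity
  `HR = exp(−β/σ)` with delta-method CIs, AIC/BIC, likelihood-ratio
  tests, and stratified treatment HRs with a df = 2 interaction LRT and an
  ordinal trend test.
* **Threshold (two-piecewise) regression** of mean HbA1c against each
  outcome: hinge model `β₁·min(x, K) + β₂·max(x − K, 0)`, breakpoint `K`
  by profile likelihood over a 0.01% grid, percentile-bootstrap CI for
  `K`, per-segment HRs, and a df = 1 curvature LRT.
* **Smooth HR curves**: natural cubic spline (df = 4) in the AFT linear
  predictor, normalized to HR = 1 at the median exposure.
* **A synthetic cohort generator** emulating an intensive-vs-standard
  glycemic-control trial: AR(1) HbA1c trajectories with hidden volatility
  strata, Weibull outcomes whose hazards carry piecewise mean-HbA1c
  effects and stratum-dependent treatment effects, and administrative
  censoring — all bit-reproducible from one seed.

## Worked example

```r
library(glycvar)

params <- cohort_params(n_patients = 8000, seed = 20)
cohort <- generate_cohort(params)
metrics <- compute_metrics(cohort$visits)

feats <- standardize(metrics[, c("hvs", "sd")])
km <- order_clusters(kmeans_fit(feats, k = 3, seed = 1), metrics$hvs)
groups <- cluster_groups(km)

dat <- cbind(cohort$patients, metrics[, c("hvs", "sd", "mean_hba1c")])
stratified_treatment_hr(dat, groups, outcome = "mace")
find_inflection(dat[groups == "medium", ], outcome = "death")
```

```
Stratified intensive-treatment hazard ratios (mace)
   group    hr ci_low ci_high  p_value    n n_events
1    low 0.715  0.529   0.967 0.029600 3044      185
2 medium 1.227  0.952   1.581 0.114000 3169      242
3   high 1.910  1.355   2.693 0.000219 1787      173
P interaction (LRT, df=2): 0.0001123   P trend: 4.427e-05

Two-piecewise threshold model (death ~ mean_hba1c)
  inflection point K = 7.37%
  HR below K: 0.378 (0.239-0.596)
  HR above K: 1.176 (0.609-2.271)
  one-line HR per 1%: 0.580;  P curvature (LRT df=1): 0.02775
```

The cohort was generated with a protective intensive-treatment effect
(true marginal HR 0.78, plus the indirect benefit of lowered mean HbA1c)
in the low-variability stratum, a harmful one (true HR 2.0) in the high
stratum, and a U-shaped mortality relation in the medium stratum with a
breakpoint at 7.44% (mortality HR 0.49 per 1% below it, 1.57 above). The
fitted analysis recovers this pattern: the treatment HR rises from 0.72
(protective) in the low-variability group to 1.91 (harmful) in the high
group with a strongly significant treatment-by-variability interaction,
and the medium group's mortality threshold lands at 7.37% with a
protective slope below it (HR 0.38 per 1%) turning neutral-to-harmful
above it, the curvature test rejecting linearity — i.e. aim low in stable
patients, but in patients with erratic HbA1c a moderate mean HbA1c is
safer than a low one.

`run_full_analysis(run_config(...))` sequences the whole pipeline
(eligibility → metrics → clustering → stratified HRs → thresholds →
curves) into a single report bundle with a reproducibility manifest, and
`write_report()` writes it as CSV + JSON. A thin CLI wrapper lives at
`inst/scripts/glycvar-cli.R` (`simulate` and `run-all` subcommands).

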