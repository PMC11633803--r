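# ductdose

Dose-constraint analysis for the parotid ducts in head-and-neck
radiotherapy.

Radiation-induced xerostomia (dry mouth) is one of the most burdensome
late toxicities of head-and-neck radiotherapy. Beyond sparing the parotid
*glands*, there is growing evidence that the dose to the parotid *ducts* —
where salivary stem/progenitor cells are thought to reside — drives
patient-reported dry mouth. `ductdose` is an R toolkit for analysts who
want to (i) identify a mean-dose threshold for a duct structure that
separates patients with and without patient-reported xerostomia, and
(ii) quantify how reliably surrogate dose estimates (e.g. from atlas-based
segmentation, when no MRI sialogram is available) classify patients
against such a constraint.

## What it computes

**Cut-point search.** PRO-CTCAE dry-mouth scores (0–4) are dichotomized at
moderate-or-worse (score ≥ 2). For a candidate threshold *c* on a 1 Gy
grid spanning the observed dose range, evaluable patients split into
groups *D* < *c* and *D* ≥ *c*; a one-sided Fisher exact test asks whether
toxicity is more frequent above the threshold:

p(c, t) = P( X ≥ x_obs | margins ),  X ~ Hypergeometric

computed per timepoint *t* (6 and 12 months). Grid values leaving fewer
than 10 evaluable patients in either group at any timepoint are excluded;
the selected constraint minimizes max_t p(c, t) (the product is available
as an alternative), with ties broken toward the lowest, most protective
dose. `scan_cutpoints()` returns a classed object with `print`,
`summary`, `coef` and `plot` methods.

**Surrogate-dose error propagation.** From a validation set of paired
reference/surrogate doses, `fit_error_model()` estimates the Gaussian
error N(μ, σ) of the surrogate. `propagate()` replays that error over a
reference dose list R times (Monte Carlo) and pools sensitivity and
specificity of constraint classification (positive = dose < constraint);
`analytic_sens_spec()` gives the closed-form limit

sens = mean over d < c of Φ((c − d − μ)/σ),
spec = mean over d ≥ c of 1 − Φ((c − d − μ)/σ).

**Agreement metrics.** `difference_stats()` summarizes reference-minus-
surrogate dose differences (mean, sample SD) and the mean distance to
agreement; `mean_distance_to_agreement()` computes the symmetric
nearest-point MDA between two contour point clouds.

**Cohort comparison.** `chisq_test()` (Yates' correction for 2×2 only),
`wilcoxon_ranksum()` and the exact `proportion_compare()` reproduce
standard cohort-characteristic comparisons.

**Synthetic cohorts.** `simulate_cohort()`, `simulate_validation_pairs()`
and `simulate_contour_pair()` generate data with the statistical structure
the analysis assumes (correlated gland/duct doses, a monotone
dose–toxicity response, per-timepoint follow-up loss, Gaussian surrogate
error), so the full pipeline is testable without patient data. Published
summary tables from a 38-patient duct-sparing trial are bundled as
fixtures (`load_fixture()`).

## Worked example

```r
library(ductdose)

# Published 14-patient atlas-validation set
t4 <- load_fixture("table4")
difference_stats(t4, "total")
#> Agreement over 14 validation pairs
#>   dose difference (reference - surrogate): 0.96 +/- 2.85 Gy
#>   mean distance to agreement: 4.46 mm

# Gaussian surrogate-dose error, propagated against the 12 Gy constraint
em <- fit_error_model(t4, "total")
pr <- propagate(t4$dose_ref[t4$structure == "total"], 12, em,
                R = 10000, seed = 7)
pr
#> Monte-Carlo error propagation: 14 patients x 10000 replicates = 140000 estimates
#>   constraint 12 Gy; error N(0.964, 2.85) Gy (add)
#>   sensitivity 67.2%, specificity 89.5% (positive = meets constraint)
analytic_sens_spec(t4$dose_ref[t4$structure == "total"], 12, em)
#> sensitivity specificity
#>   0.6739936   0.8948407

# Cut-point search on a synthetic cohort with a known 14 Gy threshold
co <- simulate_cohort(sim_config(n_patients = 400, seed = 5))
scan_cutpoints(co, "ig")
#> Mean-dose cut-point scan (ig ducts)
#>   grid: 0..29 Gy in 1 Gy steps; min group size 10; combine = max
#>   selected cut-point: 13 Gy (criterion 6.88e-31; p6mo 6.56e-32, p12mo 6.88e-31)
```

The Monte-Carlo sensitivity/specificity agree with the analytic formula to
Monte-Carlo precision; the scan recovers the simulated 14 Gy threshold to
within 1 Gy (a 400-patient cohort carries finite information about a
logistic dose–response, so the selected grid value fluctuates by about
±1 Gy across seeds).

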