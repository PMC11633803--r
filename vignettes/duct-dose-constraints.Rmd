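---
title: "Identifying and validating parotid duct dose constraints"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying and validating parotid duct dose constraints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ductdose)
```

## The analysis problem

After head-and-neck radiotherapy, patient-reported dry mouth (xerostomia)
tracks not only the mean dose to the parotid glands but also the dose to
the parotid ducts, the region where gland-repairing progenitor cells are
believed to concentrate. Two questions drive this package:

1. **Constraint identification.** Given per-patient mean duct doses and
   PRO-CTCAE dry-mouth scores at 6 and 12 months, which mean-dose
   threshold best separates patients with and without patient-reported
   toxicity?
2. **Surrogate validation.** When duct contours come from a surrogate
   (atlas-based segmentation instead of MRI sialography), how reliably do
   the surrogate doses classify a patient as meeting or failing the
   identified constraint?

## Outcome model and cut-point search

The PRO-CTCAE dry-mouth item is scored 0 (none) to 4 (very severe).
`dichotomize()` maps moderate-or-worse (2–4) to toxicity and 0–1 to no
toxicity, the prevailing convention in the patient-reported-outcome
literature; missing questionnaires stay missing and are excluded from the
affected timepoint only — the two timepoints legitimately have different
denominators.

`scan_cutpoints()` evaluates every multiple of `grid_step` (default 1 Gy)
inside the observed dose range. At each candidate `c` and timepoint,
patients split into dose `< c` versus `>= c` (the boundary patient goes
*above*: the half-open convention guarantees a partition, and published
constraints are phrased as "dose < c"). A one-sided Fisher exact test —
the exact hypergeometric tail probability that the above group has at
least its observed number of toxic patients — quantifies separation. The
test is one-sided because the scientific hypothesis is directional:
higher dose should not protect against xerostomia.

Three guards keep the scan honest:

* **Minimum group size** (default 10 per group, at every evaluated
  timepoint): cut-points near the edge of the dose distribution would
  otherwise win on unstable tiny-group tables. A timepoint with fewer
  than `2 * min_group` evaluable patients cannot satisfy this anywhere
  and is dropped with a diagnostic rather than vetoing the entire scan.
* **Joint criterion across timepoints**: the default combines the
  per-timepoint p-values by their maximum, i.e. a cut-point is only as
  good as its *worst* timepoint. The product is available as an
  alternative (`combine = "product"`); the choice is recorded in the
  result object. We default to the maximum because it cannot be rescued
  by one exceptionally strong timepoint.
* **Tie-break toward the lowest dose**: when several grid values attain
  the minimal criterion, the most protective (lowest) constraint is
  selected, which is also the deterministic choice.

No multiplicity correction is applied across the scanned grid — the scan
is an exploratory maximally-selected statistic, and its p-values should
be read as a selection criterion, not as confirmatory inference.

## Surrogate-dose error model and propagation

A validation set pairs reference doses (MRI-based contours) with
surrogate doses (atlas-based contours). `fit_error_model()` summarizes
the reference-minus-surrogate differences by their mean `mu` and sample
standard deviation `sigma` (divisor n − 1; this is the convention that
reproduces the published validation summaries from the printed
per-patient values), defining a Gaussian error model.

`propagate()` mimics using the surrogate on patients whose true doses are
known: in each of `R` replicates, every reference dose receives an
independent N(mu, sigma) perturbation, and the perturbed dose is
classified against the constraint. Meeting the constraint (dose strictly
below it) is the *positive* class. Sensitivity and specificity are pooled
over all `R * n` estimates; per-replicate counts are retained so the
dispersion across replicates can be inspected.

The perturbation is **added** to the reference dose by default. The
wording of the emulated procedure ("sampled ... and added back to the MRI
duct doses") implies addition, although the fitted difference is
reference − surrogate, which would suggest subtraction; with `mu` near
1 Gy the two conventions give different specificity. Rather than silently
resolving this tension, `sign = "subtract"` exposes the alternative, and
the analytic oracle accepts the same flag.

`analytic_sens_spec()` is the closed-form limit of the Monte-Carlo
procedure: the probability that a patient with reference dose `d` is
predicted to meet constraint `c` is `pnorm((c - d - mu)/sigma)`,
averaged over the patients truly meeting (sensitivity) or failing
(specificity) the constraint. With `sigma = 0` the indicator limits are
used. Because the replicate draws are independent, the pooled Monte-Carlo
rates converge to this oracle at rate O(1/sqrt(R n)); the test suite
checks agreement within three Monte-Carlo standard errors. A dose
configuration entirely on one side of the constraint leaves one rate
undefined; it is reported as `NA` with a diagnostic, never coerced to 0.

## Contour agreement

`mean_distance_to_agreement()` operates on contour *point clouds*: for
each point of one set, the Euclidean distance to the nearest point of the
other; the two directional means are averaged. This symmetric point-cloud
definition is the package's operational choice — commercial planning
systems compute MDA against proprietary surface reconstructions whose
definition is not public, so bundled published MDA values are treated as
data to summarize, not as targets the reimplementation must reproduce.
The implementation computes distances row-wise in exact arithmetic
(`sqrt(sum((a_i - b_j)^2))` vectorized over `j`) rather than through the
Gram-matrix identity, which loses ~1e-7 of precision to cancellation and
would violate the MDA(a, a) = 0 identity.

## The synthetic cohort generator

`simulate_cohort()` exists so that every downstream stage has a
controllable, reproducible input. Its defaults are fixed to the study
conditions the package emulates:

| parameter | default | meaning |
|---|---|---|
| `n_patients` | 38 | duct-sparing trial cohort size |
| `gland_dose_mean`, `gland_dose_sd` | 27.2, 5.7 Gy | bilateral parotid gland mean dose marginal |
| `duct_given_gland_slope`, `duct_dose_sd` | 0.5, 4 Gy | linear gland-to-duct coupling plus scatter |
| `toxicity_model` | logistic | Bernoulli(plogis((d − d50)/steepness)) per timepoint |
| `threshold_d50`, `logistic_steepness` | 14, 2 Gy | response centred at the published IG constraint |
| `followup_6mo_prob`, `followup_12mo_prob` | 33/38, 29/38 | published evaluable fractions |
| `error_mu`, `error_sigma` | 0.96, 2.9 Gy | published surrogate-error summary |

The gland–duct coupling is linear with additive Gaussian scatter and
truncation at 0 Gy: the published per-patient joint distribution is not
available, only scatter plots showing a positive association with gland
doses ~15–40 Gy and duct doses ~5–30 Gy, and the chosen slope and scatter
land the simulated doses in those ranges (duct mean ≈ 13.6 Gy). The
toxicity response is driven by the intraglandular duct dose; toxic
patients report score 3 and non-toxic patients score 1, so the
dichotomization step stays on the analysis path while outcomes remain
deterministic given the latent toxicity draw. One integer seed governs
every sub-stream, and the generator restores the caller's RNG state.

What the generator does *not* emulate: voxel-level dose distributions,
anatomically realistic contours, longitudinal score trajectories
(scores at 6 and 12 months are independent draws given the dose), or
informative missingness (follow-up loss is independent of outcome).
Passing parameter-recovery tests on this generator therefore shows the
estimator is consistent under the assumed monotone dose–response with
non-informative missingness — not that real cohorts satisfy those
assumptions.

## Numerical and design notes

* Exact tests are computed from hypergeometric distribution functions;
  the two-sided proportion comparison uses the classic tie rule (sum of
  all tables with probability ≤ the observed table's, within a 1e-7
  relative epsilon). Both are verified against full binomial-coefficient
  enumeration for every non-empty table with total count ≤ 40.
* The chi-squared cohort comparison applies Yates' continuity correction
  to 2×2 tables only; published r×c comparisons are reproduced by the
  uncorrected Pearson statistic.
* The rank-sum test uses the exact null distribution for combined
  n ≤ 20 without ties, otherwise the midrank normal approximation with
  tie and continuity correction.
* Degenerate inputs fail loudly: fewer than two validation pairs (SD
  undefined), empty point sets, zero margins, out-of-range scores, and
  cohorts too small for the group-size constraint all raise errors or
  return `NA` with a diagnostic — never a silent 0.
* Problem sizes in the test suite (e.g. 20 replicates of 400-patient
  cohorts for cut-point recovery, R = 10 000 replicates for Monte-Carlo
  convergence, 200-point clouds against the brute-force MDA oracle) were
  chosen to give stable statistical checks in seconds on one CPU.

## Worked pipeline

```{r pipeline}
# 1. Surrogate validation on the bundled published validation set
t4 <- load_fixture("table4")
difference_stats(t4, "total")
em <- fit_error_model(t4, "total")

# 2. Error propagation against the 12 Gy total-duct constraint
doses <- t4$dose_ref[t4$structure == "total"]
propagate(doses, 12, em, R = 10000, seed = 1)
analytic_sens_spec(doses, 12, em)

# 3. Cut-point identification on a synthetic cohort
co <- simulate_cohort(sim_config(n_patients = 400, seed = 1))
sc <- scan_cutpoints(co, "ig")
summary(sc)
rate_table(co, "ig", coef(sc))
```

## Known limitations

* The per-patient doses and outcomes behind the published cut-points are
  not public, so the package demonstrates the *procedure* on synthetic
  cohorts and the published summary tables; the headline published
  sensitivity/specificity values require the unpublished 38-patient dose
  list and are out of reach by construction.
* The maximally-selected cut-point is a biased, high-variance estimator
  at n ≈ 40; the recovery experiments at n = 400 characterize the
  procedure, not small-sample performance.
* The Gaussian error model is a two-moment summary; heavy-tailed or
  dose-dependent segmentation errors are not represented.
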