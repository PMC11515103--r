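---
title: "Methods: simulating composite-allocation bias in shock classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating composite-allocation bias in shock classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shockbias)
```

## The question the simulation answers

Trauma registries grade hypovolemic shock I–IV separately from heart rate
(HR), systolic blood pressure (SBP), Glasgow Coma Scale (GCS) and base
deficit (BD). When the three vital parameters are pooled into a composite by
taking the *highest* member class and that composite is compared per class
against the BD class for transfusion quantity, the comparison is not
symmetric: the maximum rule inflates composite classes, filling severe
composite classes with patients whose other parameters are normal, and those
patients drag the composite group's mean transfusion down. `shockbias`
measures this effect in a world where, by construction, every predictor
carries the same information about the outcome, so any systematic advantage
for the singleton parameter is attributable to the method, not the biology.

## Cohort model

**Dependence.** A Gaussian copula couples the five variables. Targets are
specified as Spearman rank correlations; `spearman_to_copula_param()` applies
the exact relation r = 2·sin(πρ_s/6) so that the pre-truncation sample rank
correlation is centred on the target. We interpret the experiment's
correlation settings on the rank scale because the realized values it is
judged against are themselves Spearman coefficients computed after
post-processing, slightly attenuated relative to the targets — consistent
with rank-scale targets degraded only by rounding and truncation.

**Feasibility repair.** The `unequal` setting (predictor–outcome magnitudes
0.8/0.8/0.8/0.3, predictor–predictor left at 0.55) is not jointly feasible:
after the sine transform its matrix has smallest eigenvalue ≈ −0.064. Since
the stated quantities of interest are the predictor–outcome correlations, the
repair must not move them: `validate_correlation_matrix()` uses Dykstra
alternating projections between the PD cone and the affine set holding the
outcome column fixed, adjusting only the unstated predictor–predictor
entries (they rise from ≈ 0.57 toward the value a common-factor structure
implies). An unconstrained nearest-PD projection (`Matrix::nearPD`) is used
when no entries are anchored; either way the Frobenius distance of the
repair is recorded in the run artifacts.

**Marginals.** HR, SBP, BD and transfusion are truncated normals; GCS is a
discrete trimodal mixture on 3–15. The defaults are *placeholders*: the
registry-derived means and SDs underlying the original comparison are not
public, so values were chosen once to be clinically plausible for a
multitrauma population and are flagged `placeholder-marginals` in every
output.

| variable | default | bounds | rounding | why |
|---|---|---|---|---|
| hr | N(95, 25) | [20, 220] | integer | tachycardia-shifted vital sign; monitors cap near 220 |
| sbp | N(120, 30) | [50, 250] | integer | normotensive centre with hypotensive tail |
| gcs | trimodal, modes 3/7/15 | {3..15} | integer | severe-TBI, intermediate and normal clusters |
| bd | N(3.5, 4.5) | [−8, 30] mmol/L | none | mild base deficit typical, negative values (base excess) possible |
| transfusion | N(2, 4) | [0, 60] units pRBC | none | most patients near zero, long right tail after bounding |

The GCS mixture weights (0.245, 0.295, 0.46) and spreads (1.2, 2.0, 2.0) are
constrained so the analytic mass below 12 is ≈ 0.55 (a majority of the
emulated population below GCS 12) while keeping 3, 7 and 15 local modes of
the resulting pmf; `gcs_pmf()` exposes the distribution so the constraint is
testable analytically rather than by simulation alone.

**Truncation.** Two mechanisms are implemented because "bounded to
physiological limits" can mean either. `quantile` (default) inverts the CDF
of the *truncated* law: no point mass at the bounds, ranks undisturbed.
`clip` takes the unrestricted quantile and clips: a point mass appears at
the bounds (≈ 31% of transfusion at 0 under the default marginals), creating
ties that attenuate rank correlations a few hundredths — close to the
attenuation the original experiment reported, which suggests it clipped. Both
modes are exercised by the acceptance tests; the substantive conclusions are
identical.

**Transfusion stays continuous** by default. Rounding it to whole units would
add rank ties that silently shift Spearman values; a `round_to_integer` flag
exists for sensitivity analysis.

## Classification

Thresholds live in `threshold_table()` as data, with per-break strictness,
because the printed source grading has overlapping endpoints. The encoded
reading follows the explicitly marked entries (BD's "≤ 2.0 / > 2.0–6.0 / …"
and HR's "> 140" for class IV): HR < 100 → I, [100, 120] → II, (120, 140] →
III, > 140 → IV; SBP ≥ 110 → I, [100, 110) → II, [90, 100) → III, < 90 → IV;
BD ≤ 2 → I, (2, 6] → II, (6, 10] → III, > 10 → IV. HR and SBP are rounded to
integers before grading, so the boundary convention touches ≈ 0.5% of
patients at most.

A GCS of 15 maps to class I or II (distinguished only by qualitative mental
status in the source grading); patients are redistributed half and half. The
default is an independent fair coin per patient (`bernoulli`), drawn from a
seed substream separate from the copula stream so classification noise never
perturbs cohort values; `exact-half` performs a seeded permutation split for
sensitivity analysis. An intubation rule (GCS graded IV when intubated
pre-hospital) cannot be simulated — no intubation variable exists — and is a
known divergence from the original registry procedure.

## The comparison under audit

For each class II–IV (class I is computed but not emphasized), transfusion
quantity is compared between patients assigned the class by the singleton
parameter and patients assigned the class by the composite, with a classical
pooled-variance two-sample t-test (`welch = TRUE` switches to Welch). The two
groups overlap in membership, making observations non-independent; the test
is applied *naively on purpose* — it is the method being audited — and every
summary carries an `overlapping-groups-ttest` caveat. No multiplicity
correction is applied across classes, again for fidelity. Degenerate groups
(n < 2, or zero pooled variance) are flagged, never fabricated.

## Determinism and seeds

Every run is a pure function of its configuration. A master seed fans out via
`derive_seed()` (a fixed affine-mod counter scheme) to per-scenario seeds —
by correlation *structure*, so `equal`/`swap-equal` share a cohort draw and
differ only in composite membership — and within a scenario to the copula
stream and the GCS-split stream. Reports contain no timestamps and are
written at full numeric precision, so regenerating a report from a saved
cohort (`replay_run()`) reproduces it byte for byte.

## What a green test establishes — and what it does not

The generator emulates marginal shapes, physiological bounds, a realistic
class imbalance and a controlled dependence structure. It does **not**
emulate: real registry missingness, measurement error, pre-hospital
intubation, traumatic-brain-injury subgroups with low GCS but no hemorrhage,
integer-valued transfusion, or any true (unknown) predictor–outcome
correlations. Passing tests therefore establish that the *allocation
machinery itself* biases the comparison — including when the singleton's
correlation is handicapped (0.3 vs 0.8) and when HR replaces BD as the
singleton — not that any particular parameter is clinically superior or
inferior.

Two quantitative caveats follow from the placeholder marginals. First, the
realized post-processing correlations and the joint-class fraction land near,
but not exactly on, the originally reported values; tolerances in the
acceptance tests absorb that. Second, in the `unequal` scenario the class-IV
mean difference is small (the handicapped singleton retains only its
grouping advantage) and its per-class t-test is not reliably significant at
n = 16,305 under these marginals, although its *direction* — singleton above
composite — is stable across seeds; the acceptance suite requires
significance where the predictors are exchangeable (equal-type scenarios) and
direction everywhere, and the strict all-scenarios-significant rate is
reported by `scripts/acceptance.R` so the distinction stays visible.

## Worked run

```{r example}
s <- run_scenario(scenario_config("equal", seed = 42))
round(s$postprocessing_spearman, 3)
round(s$joint_class_fraction, 4)
s$comparisons[, c("class", "n_singleton", "n_composite",
                  "mean_singleton", "mean_composite", "p_value")]
```

```{r figures, fig.width = 7, fig.height = 5}
cohort <- simulate_cohort(scenario_config("equal", seed = 42))
plot_cohort_histograms(cohort)
plot_class_means(s)
```
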