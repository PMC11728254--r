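---
title: "Methods: the SIL score and its validation pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the SIL score and its validation pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Sepsis mortality is high and strongly time-dependent: patients at high risk
of in-hospital death need to be recognised at emergency-department triage,
before laboratory panels are complete. The scales commonly available at
triage are either purely clinical (qSOFA, NEWS) or require a full laboratory
work-up (SOFA). The SIL score occupies the middle ground: it combines one
haemodynamic variable available at the bedside — the shock index, heart rate
divided by systolic blood pressure — with one fast metabolic variable,
arterial lactate.

## The score

Each component is binned into 0–3 points and the two sub-scores are summed:

| Shock index | PIS | Lactate (mmol/L) | PL |
|-------------|-----|------------------|----|
| 0–0.90      | 0   | 0–2.00           | 0  |
| 0.91–1.35   | 1   | 2.01–4.00        | 1  |
| 1.36–1.80   | 2   | 4.01–6.00        | 2  |
| ≥ 1.81      | 3   | ≥ 6.01           | 3  |

SIL = PIS + PL, range 0–6, higher predicting higher in-hospital mortality.

**Rounding convention.** The printed band edges leave gaps on the real line
(0.90 vs 0.91, 2.00 vs 2.01, …). `silscore` rounds both the shock index and
lactate to two decimal places before binning; at that precision the closed
printed intervals tile the non-negative line exactly, so binning is total,
deterministic and free of tie-break ambiguity. Whether the original analysts
rounded before binning is not documented; the two-decimal convention is this
package's design choice, stated once here.

**Comparators.** NEWS is computed from the pinned published seven-component
table; the default is NEWS2 Scale 1, with the 2012 table selectable. On the
fields representable in this package's schema the two versions score
identically (the revisions concern the hypercapnic SpO2 scale and "new
confusion", neither of which the schema carries), and the test suite asserts
that equivalence rather than leaving it folklore. qSOFA scores one point
each for respiratory rate ≥ 22, systolic BP ≤ 100, and altered mentation,
operationalised as GCS < 15 or any AVPU level other than alert. SOFA sums
the six 1996 organ-system sub-scores; vasopressor dosing is accepted as a
pre-binned category because triage data sets record the category, not a
µg/kg/min rate, and the respiratory sub-score does not condition on
ventilation status (the schema has no ventilation flag). Missing SOFA
components are handled strictly by default — the record's SOFA is absent and
excluded from SOFA analyses, with the count logged — because silently
imputing zero points is anticonservative; a permissive mode does exactly
that imputation for users who want it.

## Accuracy analysis

A positive test is `score >= cutoff` for every scale (all four are
higher-is-worse). Sensitivity and specificity carry binomial confidence
intervals — Wald by default, matching "standard formulas for a binomial
proportion"; Wilson by option. Predictive values are prevalence-adjusted via
Bayes' theorem,

$$PPV = \frac{se\,p}{se\,p + (1-sp)(1-p)}, \qquad
  NPV = \frac{sp\,(1-p)}{sp\,(1-p) + (1-se)\,p},$$

which reduces exactly to the raw-count predictive values when `p` is the
sample prevalence (a property the tests check on random tables). The cutoffs
behind the published accuracy table are not reported, so `accuracy_report()`
scans every observed cutoff and reports the Youden-optimal one by default;
a fixed cutoff can be supplied.

**A documented discrepancy.** Applying the adjustment formulas to the
published SIL sensitivity 0.694, specificity 0.678 and prevalence 61/299
gives 0.356 and 0.896 — the published table prints 0.362 and 0.893 in the
*opposite* columns (and the same inversion reproduces on the qSOFA, NEWS and
SOFA rows). `silscore` computes per the formulas and does not replicate the
swap.

**AUC.** The empirical AUC is the tie-corrected Mann–Whitney concordance
probability, computed in closed form from a stratum table or by midranks
from per-patient scores; both routes are checked against an $O(mn)$
brute-force pair-counting oracle. Confidence intervals use the DeLong
structural-component variance (the default of the tooling the original
analysis names), with a seeded percentile bootstrap as an alternative;
paired curves are compared with the paired DeLong z-test. The AUC of the
published stratum table is 10789/14518 ≈ 0.7431, slightly below the
published full-data 0.754; the stratum table is the only machine-readable
form of the data, and whether the published figure used a different analysis
set cannot be resolved from the text, so tests anchor on the 0.7431 oracle
value and treat 0.754 as the approximate published anchor.

**Associations.** Comorbidity and diagnosis-class associations use the
cross-product odds ratio with a Wald log-scale CI and Haldane–Anscombe 0.5
correction when a cell is zero, plus the Yates-corrected chi-square test
(correction configurable off). Cross-products of the published 2×2 counts
give 4.13 (renal insufficiency) and 6.01 (septic shock) against printed 4.11
and 5.94; the original estimator is unstated, so the acceptance check is the
2% property band, not exact equality. No multiple-testing adjustment is
applied, mirroring the original analysis; reported p-values are unadjusted.

## Calibration

The published analysis bootstrapped its calibration curves (1000
repetitions) without stating the construction. `fit_calibration()` uses the
simplest procedure consistent with calibration plots of a discrete score:
a single-predictor logistic recalibration of death on the score supplies
per-bin predicted risk; bins are the score values, with bins under 5
patients merged into the adjacent lower bin (tiny top strata — n = 2 and 3
occur in the reference cohort — make raw proportions meaningless); per-bin
observed mortality is recomputed on each of `reps` seeded resamples with
replacement, and the 2.5/97.5 percentiles form the band. The seed is
mandatory because the band is a resampling quantity; a fixed seed gives a
bit-identical curve.

## The synthetic cohort generator

No patient data accompany the published study, so `generate_cohort()`
produces seeded cohorts whose *stated* structure matches the published
summary tables:

- SIL stratum probabilities 87, 104, 52, 36, 15, 2, 3 over values 0–6
  (n = 299) and per-stratum mortality 6/87 … 3/3 — together implying 20.4%
  overall mortality and a closed-form SIL AUC of 0.7431;
- male fraction 124/299, septic-shock fraction 106/299, comorbidity
  prevalences from the published characteristics table;
- ages centred near the published medians (survivors ~72, deaths ~74).

Construction choices where the publication is silent:

- the stratum total is split uniformly over the valid (PIS, PL) pairs
  (maximum-entropy choice consistent with the published marginal);
- shock index and lactate are drawn uniformly inside the band implied by the
  sub-score; the unbounded top bands use truncated exponentials with
  physiologic caps (shock index ≤ 3.0, rate 2; lactate ≤ 20 mmol/L,
  rate 0.3); the zero-point bands start at physiologic floors (shock index
  0.35, lactate 0.30) rather than zero;
- heart rate is back-solved as shock index × (integer systolic BP drawn from
  a physiologic window), so recomputing the rounded shock index reproduces
  the assigned stratum exactly — `round_trip_check()` is 0 by construction
  and the tests corrupt a record deliberately to prove the check bites;
- septic shock is coupled to the stratum through per-stratum probabilities
  proportional to stratum mortality, calibrated (with clipping at 1) so the
  configured marginal holds exactly in expectation;
- the NEWS/qSOFA/SOFA inputs load on a shared latent severity variable
  (standardised stratum × loading 0.5 + standard normal noise) so comparator
  analyses are exercised with plausible correlation. The survivor /
  non-survivor distributions of the comparator scores are published only as
  medians and IQRs; this coupling is a construction, not a copy.

**What a green test does and does not establish.** The generator reproduces
the published *marginals* (stratum sizes, stratum mortality, sex, shock,
comorbidities) and its tests verify recovery within three binomial standard
errors at n = 50 000. It does not claim the true joint distribution of
vitals, labs and outcome — so pipeline results on synthetic cohorts validate
the *machinery* (scoring, accuracy statistics, calibration, reproducibility),
not clinical conclusions about comparator scales.

## Numerical choices and degenerate inputs

- AUC with a single outcome class is an error, never 0.5 by fiat; a constant
  score gives exactly 0.5 via the tie term.
- DeLong CIs are clipped to [0, 1]; at perfect separation the variance
  collapses and the degenerate CI is the point.
- `compare_auc` of two identical score vectors returns p = 1 (zero variance
  of a zero difference); zero variance with a non-zero difference returns
  p = 0 rather than dividing by zero.
- Predictive values with a zero denominator return `NaN` with a warning —
  an undefined value, not a crash.
- `read_cohort` rejects rows (with file line numbers) whose mandatory fields
  are unparseable or out of contract, and loads the remainder; a file whose
  every row is rejected is an error.
- Pipelines never write timestamps, so identical config + seed gives a
  byte-identical report bundle; the tests compare bundles byte-for-byte.

## Known limitations

- The SIL AUC on the stratum fixture (0.7431) deliberately does not
  reproduce the published full-data 0.754; see above.
- The acceptance fixture value 68.8% (deaths with septic shock, 42/61 =
  68.85%) appears truncated in the publication; the tests compare to the
  printed precision.
- The comparator-score joint distribution in the generator is a modelling
  construction; conclusions about NEWS/qSOFA/SOFA relative performance on
  synthetic data reflect the generator's latent-severity loading, not
  clinical reality.
- Sample-size/power computation for paired ROC designs and the derivation of
  the expected-mortality column (0–6 → 11.8%…90.4%) are out of scope; the
  latter ships as packaged constants for expected-vs-found comparisons.
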