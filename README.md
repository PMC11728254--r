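# silscore

Emergency-department triage must identify, within minutes, which patients
with suspected sepsis are likely to die in hospital. `silscore` implements
the **SIL score** — shock index (heart rate / systolic blood pressure)
binned to 0–3 points plus arterial lactate binned to 0–3 points, total 0–6 —
together with the NEWS, qSOFA and SOFA comparator scales, and the complete
diagnostic-accuracy pipeline used to validate such ordinal severity scores
against binary in-hospital mortality.

The package is aimed at emergency-medicine and biostatistics researchers who
want to (a) compute the four scores from raw triage vitals and labs,
(b) reproduce a score-validation analysis — sensitivity/specificity with
binomial CIs, prevalence-adjusted predictive values, empirical ROC/AUC with
DeLong or bootstrap CIs, paired AUC comparison, odds ratios, chi-square
tests, stratum mortality tables, bootstrap calibration curves — and
(c) exercise all of it on seeded synthetic cohorts that match the published
summary structure of a 299-patient validation cohort (20.4% mortality,
35.5% septic shock).

## The statistic at the core

For a discrete score $S$ and death indicator $D$, the empirical AUC is the
tie-corrected concordance probability

$$\mathrm{AUC} = \Pr(S_{\text{death}} > S_{\text{surv}})
  + \tfrac12 \Pr(S_{\text{death}} = S_{\text{surv}}),$$

estimated by midranks, with DeLong structural-component variances for CIs
and paired curve comparison. Predictive values are prevalence-adjusted by
Bayes' theorem: $NPV = sp(1-p)\,/\,[sp(1-p) + (1-se)p]$, and symmetrically
for PPV.

## Worked example

```r
library(silscore)

# one patient: HR 118, SBP 95, lactate 3.4 mmol/L
sil_points(shock_index(118, 95), 3.4)
#>  shock_index lactate pis pl total
#>         1.24     3.4   1  1     2

# a full synthetic validation cohort, scored and evaluated
co  <- generate_cohort(cohort_config(), seed = 2026)   # n = 299
sc  <- score_cohort(co)
accuracy_report(sc$sil_total, sc$died, cutoff = 3)
#> Accuracy at cutoff >= 3 (prevalence 0.161)
#>   sensitivity 0.479 (0.338-0.620)
#>   specificity 0.892 (0.854-0.931)
#>   PPV 0.460  NPV 0.900 (prevalence-adjusted)
#>   counts: tp 23 fp 27 fn 25 tn 224

auc_ci(sc$sil_total, sc$died)
#> AUC 0.798 (95% CI 0.733-0.863, delong)

cmp <- compare_auc(sc$sil_total, sc$news, sc$died)   # paired DeLong
sprintf("SIL vs NEWS: dAUC %+.3f, p = %.3f", cmp$delta, cmp$p_value)
#> "SIL vs NEWS: dAUC +0.129, p = 0.003"
```

The accuracy report reads: dichotomising SIL at ≥ 3 on this simulated cohort
catches 47.9% of eventual deaths while ruling in few survivors (specificity
89.2%); a negative test leaves a 10% residual mortality risk at this
cohort's 16.1% prevalence. The paired DeLong test says SIL discriminates
mortality better than NEWS on the same patients (p = 0.003). Numbers vary
with the seed — the generator reproduces the published cohort's structure,
not a fixed dataset.

The published stratum table ships as a fixture:

```r
tab <- reference_stratum_table()
empirical_auc(tab)          # 0.7431464 — closed-form AUC of the table
stratum_mortality(tab)$overall_pct   # 20.40134 (61/299)
```

## Pipeline and CLI

`run_pipeline(run_config(...))` runs simulate → score → evaluate →
calibrate → report and writes a byte-reproducible bundle (scored cohort,
accuracy/AUC/ROC/calibration/stratum CSVs, text report, JSON manifest
echoing the seed). The same verbs are scriptable:

```sh
Rscript inst/cli/silscore.R simulate --seed 7 --n 299 --out run/
Rscript inst/cli/silscore.R all --seed 7 --out run/
```

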