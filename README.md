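# cxcl13index

Stratification of clinically and radiologically isolated syndrome
(CIS/RIS) patients by intrathecal CXCL13 production, and evaluation of
that stratification as a predictor of later multiple sclerosis (MS)
activity.

## Background

CXCL13 is the dominant B-cell chemoattractant; its intrathecal
production marks B-cell recruitment into the CNS and is a candidate
biomarker for predicting disease activity after a first demyelinating
event. Measuring CSF CXCL13 alone conflates intrathecal synthesis with
passive transfer of serum CXCL13 across a leaky blood–CSF barrier, so
the analysis centres on the **CXCL13 index**,

```
I_CXCL13 = (CXCL13_CSF / CXCL13_serum) / (albumin_CSF / albumin_serum)
         = Q_CXCL13 / Q_albumin
```

the CSF/serum CXCL13 quotient normalised by the albumin quotient, the
standard barrier-integrity correction. Patients are stratified by a dual
threshold system:

* index available: **high** if `I_CXCL13 > 30`, **low** if `< 20`,
  indeterminate in between;
* serum unavailable (index not computable): **high** if CSF CXCL13
  `> 14 pg/mL`, **low** if `< 5 pg/mL`, indeterminate in between.

The CSF-only rule is a harmonization fallback justified by the observed
near-perfect concordance between the two rules outside the 5–14 pg/mL
band. Indeterminate patients are excluded from the group comparisons.

The package computes indices and stratification, builds the
group-comparison summary table (Kruskal–Wallis for continuous
variables, two-sided Fisher exact tests — by direct hypergeometric
enumeration — for binary ones), cross-tabulates the stratification
against MS-activity endpoints (CDMS conversion, clinical attacks,
lesion-positive MRIs) with exact Clopper–Pearson intervals, and fits
the CSF CXCL13 versus total nucleated cell count regression. A seeded
synthetic-cohort generator with the published group structure makes the
whole pipeline testable without patient-level data.

## Worked example

`reference_cohort()` is a deterministic 37-patient cohort encoding the
published group-level counts (20 index-low, 17 index-high patients).

```r
library(cxcl13index)
cohort <- reference_cohort()
report <- run_analysis(cohort)
cat(render_report(report, "markdown"))
```

Selected rows of the output:

```
| Variable                         | low       | high      | p-value | sig |
| Converted to CDMS (%)            | 2 (10.0)  | 14 (82.4) | <0.001  | *** |
| OCB positive (%)                 | 13 (65.0) | 16 (94.1) | 0.048   | *   |
| One or more clinical attacks (%) | 1 (5.0)   | 9 (52.9)  | 0.002   | **  |

| Outcome     | Sensitivity      | Specificity      | TP | FP | TN | FN |
| cdms        | 0.88 (0.62-0.98) | 0.86 (0.64-0.97) | 14 | 3  | 18 | 2  |
| attacks     | 0.90 (0.55-1.00) | 0.70 (0.50-0.86) | 9  | 8  | 19 | 1  |
| new_lesions | 0.93 (0.66-1.00) | 0.83 (0.61-0.95) | 13 | 4  | 19 | 1  |
```

Reading: 82.4% of index-high patients converted to clinically definite
MS against 10.0% of index-low patients (two-sided Fisher exact
p < 0.001); predicting conversion by "index-high" has sensitivity
14/16 = 0.88 and specificity 18/21 = 0.86 with exact 95% intervals in
parentheses.

The analysis workflow lives under `analysis/` as numbered stages —
`01_simulate_cohort.R` (draw the synthetic cohort and check its
calibration), `02_stratify_cohort.R`, `03_group_comparison.R`,
`04_diagnostic_performance.R` — each a thin driver over the package
functions that writes its tables under `results/`.

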