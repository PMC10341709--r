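---
title: "Methods: CXCL13-index stratification and its synthetic test bed"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CXCL13-index stratification and its synthetic test bed}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cxcl13index)
```

## The model

Intrathecal CXCL13 production is quantified by the CXCL13 index

$$ I_{CXCL13} \;=\; \frac{CXCL13_{CSF}/CXCL13_{serum}}
                        {albumin_{CSF}/albumin_{serum}}
            \;=\; \frac{Q_{CXCL13}}{Q_{albumin}}, $$

the CSF/serum chemokine quotient normalised by the albumin quotient.
Albumin is synthesised only peripherally, so $Q_{albumin}$ measures
blood–CSF barrier permeability; dividing by it corrects the chemokine
quotient for passive transfer of serum CXCL13 into the CSF. The index
is dimensionless and invariant under any common rescaling of the two
albumin or the two CXCL13 measurements, which is why the cohort format
only requires the albumin pair to share *a* unit, not a particular one.

Stratification uses a dual threshold system. With the index available,
$I_{CXCL13} > 30$ is high and $< 20$ is low. When serum was never
banked the index cannot be formed and a CSF-only fallback applies:
CSF CXCL13 $> 14$ pg/mL is high, $< 5$ pg/mL low. Both systems leave an
indeterminate middle zone; indeterminate patients are retained in the
stratification output but excluded from every group comparison and
confusion table. The fallback cuts are consumed as fixed constants of a
`threshold_policy()` — they were established on an earlier clinical
series and re-deriving them from data is out of scope here.

Two boundary decisions are ours rather than forced by the threshold
definitions. First, values exactly equal to a cut are classified
indeterminate: the rules are stated strictly as "above"/"below", ties
are measure-zero for continuous assays, and the conservative reading
avoids manufacturing a definite label from an undefined case. Second,
when both rules are computable the index rule wins; the CSF-only rule
exists only to harmonize patients whose index cannot be formed.

## Outcomes and diagnostic performance

Three binary endpoints are evaluated against the stratification:
conversion to clinically definite MS (CDMS, a second clinical attack
under the Poser criteria, consumed as a recorded boolean), one or more
clinical attacks, and one or more lesion-positive surveillance MRIs.
Patients with no MRIs performed count as negative for the lesion
endpoint — with lesion status unobservable, group-count bookkeeping
only closes if they sit in the negative class, and that is how the
motivating analysis's own tallies reconcile. The screening-adjusted
activity measure divides lesion-positive MRIs by total MRI visits and
is undefined (excluded from medians) for patients without MRIs.

`diagnostic_performance()` uses the standard definitions
(sensitivity $tp/(tp+fn)$, specificity $tn/(tn+fp)$, and the predictive
values) with two-sided exact Clopper–Pearson intervals from the beta
quantile closed form. The motivating report prints no intervals, but a
diagnostic-performance table without them would not support any
judgement at $n \approx 37$; at these sizes the intervals span roughly
$\pm 0.15$. Its printed sensitivity/specificity columns are also
internally inconsistent with their own counts (they match with the two
columns exchanged), so this package reports the standard formulas
applied to the counts and does not reproduce those two columns
as-labelled. A zero denominator yields a flagged-undefined estimate,
never a silent `NaN`.

## Hypothesis tests

The two-sided Fisher exact test is implemented directly: the
hypergeometric support of a 2×2 table with fixed margins is enumerated,
point probabilities are computed via `lgamma`, and the p-value sums all
tables whose probability does not exceed the observed table's, with a
relative slack of $10^{-7}$ so floating-point noise cannot split a tie.
Accumulation uses Kahan compensated summation. The two-sided
"probability $\le$ observed" rule was chosen because it exactly
reproduces the published p-values for the attack (0.002) and OCB
(0.048) contrasts; a one-sided test does not (it gives 0.001 for the
attack table). The test-to-variable assignment follows the evident
practice of the published table — Fisher for binary variables,
Kruskal–Wallis for continuous ones — rather than its caption's
(transposed) wording. No multiple-testing correction is applied,
matching the reporting being emulated. An exhaustive-enumeration oracle
and `stats::fisher.test` serve as independent cross-checks in the test
suite only.

Kruskal–Wallis (tie-corrected H, $\chi^2_{k-1}$ approximation) and the
ordinary least-squares fit with $R^2$ and slope t-test delegate to
`stats::kruskal.test()` and `stats::lm()`; these are standard steps,
not contributions, and reimplementing them would only add defect
surface.

## The synthetic cohort generator

No patient-level data are deposited for the motivating series, so the
generator's defaults encode its printed group structure as the study
conditions: group sizes 20 low / 17 high; log-normal index and CSF
CXCL13 distributions with the printed medians (5.99 / 67.07 and
2.02 / 17.83 pg/mL) and log-scale spreads back-solved from the printed
IQRs under log-normality ($\sigma = \log(q_{75}/q_{25}) / (2 \cdot
0.6745)$); serum availability 30% / 41.2%; Bernoulli outcome rates
(CDMS 10% / 82.4%, attacks 5% / 52.9%, OCB 65% / 94.1%); Poisson MRI
counts at roughly the printed median MRIs per median follow-up year
(0.44 / 0.63 per patient-year) with per-MRI lesion Bernoullis
(0.02 / 0.33); follow-up as $5 + \mathrm{Gamma}(2)$ years so every
patient meets the five-year eligibility floor, scaled to the printed
medians. Concentrations are positive and right-skewed, hence
log-normal; the albumin quotient (median 0.005, $\sigma_{\log} = 0.4$)
and serum albumin (4100 mg/dL) are typical adult values, and serum
CXCL13 is derived from the latent index so the recomputed index
reproduces it exactly.

Design choices worth flagging:

* **Index–CSF correlation.** The latent log index and log CSF
  concentration are drawn bivariate-normal with correlation 0.9 within
  a group. The CSF-only fallback exists because elevated indices were
  never observed below 5 pg/mL and always above 14 pg/mL in the series
  that fixed the cuts; independent draws would understate that
  concordance badly. At 0.9 the simulated agreement outside the band is
  ≈95%, consistent with a near-deterministic relationship observed
  through assay noise.
* **Indeterminate arm.** Nothing is published about the indeterminate
  patients' distributions, so they draw the index uniformly on (20, 30),
  CSF uniformly on (5, 14) pg/mL, and outcome rates midway between the
  groups (their observed activity was described as intermediate).
* **Outcome independence.** Outcomes are independent Bernoullis given
  the group; the real joint distribution (a CDMS conversion entails an
  attack) is not published, so within-patient correlation is
  understated. Confusion-table and rate checks are unaffected; any
  analysis of outcome co-occurrence would be.
* **TNC model.** $TNC = 2 + 0.3 \cdot CXCL13_{CSF} + \varepsilon$,
  $\varepsilon \sim N(0, 12)$, truncated at 0 and rounded to whole
  cells/µL. The noise SD was calibrated once, by simulation at the
  37-patient study size, so the median $R^2$ of the OLS fit sits at the
  published 0.13 (the printed $R^2$ is not recomputable without
  patient-level data; it is an emulation target for the simulator).
* **Substreams.** Each patient's draws come from an independent RNG
  substream whose seed is an avalanche hash of (global seed, patient
  id), with group-blocked ids. Enlarging a group never perturbs
  previously drawn patients, and hashing matters: seeding the Mersenne
  Twister with consecutive integers leaves measurable correlation
  between patients' early draws, which we observed as a percent-level
  bias in a generated outcome rate before switching to hashed seeds.

What passing tests on this generator do **not** show: robustness to
assay censoring at detection limits, non-log-normal tails, correlated
outcomes, informative MRI scheduling (high-activity patients are
scanned more, which the generator reflects only through the group MRI
rate), or treatment effects on outcome rates. The generator is a test
bed for the pipeline's arithmetic and inferential machinery, not a
disease model.

## Numerical choices and degenerate inputs

* Index internal consistency (`index = q_cxcl13 / q_albumin`) is exact
  arithmetic; the declared tolerance for checks is relative $10^{-9}$.
* Fisher: zero margin → degenerate flag with $p = 1$ (the conditional
  distribution is a point mass).
* Kruskal–Wallis: all observations tied → $H = 0$, $p = 1$ rather than
  an error, since a constant variable is a legitimate summary-table row.
* OLS: constant $x$ → error (undefined slope); perfect fit → $R^2 = 1$
  without the advisory warning `summary.lm` emits.
* Empty or single-group cohorts: reports are still produced, with
  group tests marked not-applicable and undefined performance measures
  flagged; empty-group percentage cells render as `0 (-)`.
* Rendering follows the emulated table style: percents to 1 decimal,
  medians/IQRs and means/SDs to 2, p-values to 3 with a `<0.001` floor,
  and significance marks `*` ($p<0.05$), `**` ($p<0.01$), `***`
  ($p<0.001$).

## Problem sizes used by the tests and acceptance script

Monte-Carlo checks run at sizes chosen to make their tolerances
meaningful while keeping the suite quick: calibration and recovery at
10,000 patients per group (binomial 2-SE tolerances of ±0.5–1%), the
Kruskal–Wallis type-I-error check at 1,000 null replicates (95% band
0.037–0.064 around 0.05), the $R^2$ bracket over 60 study-sized
replicates, and the exhaustive Fisher-vs-oracle sweep over all 135,751
2×2 tables with total $N \le 40$.

## Known limitations

The published cohort's own patient counts do not fully reconcile (29
CSF-only plus 18 index patients, nine intermediates excluded, against a
37-patient comparison table and a 13-patient serum-available row); the
data model makes no attempt to resolve this and works with whatever
cohort it is given. The reference cohort bundled for worked examples
reproduces group-level margins only — joint structure across variables
within a group is arbitrary, so only marginal counts, rates, 2×2 tables
and exact tests computed from it are meaningful. Threshold cuts are
taken as given, with no ROC analysis over the continuous index; and the
pipeline evaluates association, not calibration or clinical utility, of
the stratification.
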