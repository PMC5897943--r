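---
title: "Predicting PD-1 immunotherapy response from molecular profiles: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting PD-1 immunotherapy response from molecular profiles: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pd1tree)
```

## The problem

Non-small cell lung cancer (NSCLC) patients treated with PD-1 checkpoint
inhibitors such as pembrolizumab separate into responders and
non-responders, and immunohistochemical PD-L1 positivity alone predicts
that separation poorly. The approach implemented here instead scores each
patient on a simulated 24-molecule expression profile — PD-L1, nine
dendritic-cell-trafficking chemokines, and fourteen tumor-derived
immunosuppressive molecules (ISMs) — and feeds three summary quantities
into a fixed decision tree.

Every expression value is a *percent change* of the patient-specific
disease-state steady concentration $D$ against a non-tumorigenic baseline
control $C$ (both in µM):

$$\mathrm{pct} = \left(\frac{D}{C} - 1\right) \times 100.$$

The chemokine profile is summarized into a **dendritic-cell infiltration
index**, a weighted sum $\sum_i w_i \,\mathrm{pct}_i$ over the nine
chemokines with nonnegative weights normalized to 1. The per-chemokine
weights used for the published per-patient index values were not released;
the package defaults to uniform weights $w_i = 1/9$ (overridable via
`dc_weights()` / `read_dc_weights()`). For the one patient whose chemokine
profile was published, the uniform-weight index is 24.3 against published
index values variously printed as 23.8, 23.9, and 23.81 — so the true
weights are mildly non-uniform and unrecoverable from a single profile.
This matters only for cohorts generated here; the packaged reference cohort
carries its published per-patient index values, which the classifier
consumes directly.

## The decision tree

`classify_patient()` applies three steps with four cutoffs
(`pd_thresholds()`, defaults in percent):

1. **Step 1** — PD-L1 < 29.0: non-responder. PD-L1 *equal to or greater
   than* the cutoff proceeds.
2. **Step 2** — DC index < 20.0: non-responder (2a); DC index > 60.0:
   responder (2b). Values exactly at either bound proceed to step 3 (both
   tests are strict).
3. **Step 3** — if any of the 14 ISMs exceeds the patient's PD-L1 by
   strictly more than 5.0 percentage points: non-responder (3a), with the
   triggering molecules recorded; otherwise responder (3b).

Step 3 deserves a note. The published wording describes two symmetric
branches ("higher than PD-L1 by a margin greater than 5%" → non-responder;
"lower than PD-L1 by a margin greater than 5%" → responder), which is not
exhaustive for excesses in $[-5, 5]$. The rule implemented — non-responder
iff *any* ISM exceeds PD-L1 + 5, else responder — is the only reading that
reproduces every published label: one reference responder carries an IL6
excess of +3.63, inside the ambiguous band, and is labeled responder.

The per-step tallies report all patients; the published figure-caption
counts drop the four patients whose prediction mismatches the clinical
outcome, so `classify_cohort()` returns both `step_counts` and
`matched_step_counts`.

```{r tree}
cohort <- table1_cohort()
cls <- classify_cohort(cohort)
cls$step_counts
```

## Concordance statistics

`concordance_report()` computes per-dataset and overall match scores
(percent agreement between predicted and clinical labels), clinical and
predicted responder rates, the mismatching patient IDs, and three
discovery-vs-validation 2×2 comparisons.

Two conventions were fixed by reverse-engineering the published p-values:

* The match/mismatch comparison uses the two-sided **Fisher exact test**
  with the "point probability ≤ observed" rule (`fisher_exact_2x2()`,
  implemented directly from the hypergeometric distribution); on
  [[12, 1], [13, 3]] this gives p = 0.6059.
* The responder-rate comparisons use the **uncorrected Pearson chi-square**
  (`chi_square_2x2()`); on [[5, 8], [6, 10]] this gives p = 0.9577. A
  simple "exact test when sparse" policy keyed at expected counts below 5
  would have routed this table (minimum expected count 4.93) to Fisher, so
  the report assigns tests by comparison kind rather than by a count
  threshold; `compare_2x2()` offers an automatic chooser switching to
  Fisher below an expected count of 3.
* The published p = 0.2642 for the predicted-rate table [[4, 9], [9, 7]]
  is not reproduced by the uncorrected chi-square (0.1700), Yates-corrected
  chi-square (0.3189), or Fisher (0.2759); the report states its computed
  value and this discrepancy is documented rather than forced.

Rounding for display follows the published values: match scores use
standard half-even rounding (92.31 → 92.3, 81.25 → 81.2) while responder
rates round half-up (`round_half_up()`: 56.25 → 56.3, 30.77 → 30.8). The
published one-decimal values are internally inconsistent under any single
rule — 81.25 was printed as 81.2 but 56.25 as 56.3 — and this split is the
only convention matching all four. All returned values keep full
precision; rounding happens at report time only.

```{r concordance}
concordance_report(cohort, cls)
```

## The reduced signaling network

The original study annotated patient mutation profiles into a large
proprietary cancer network. The package ships instead a deliberately
reduced, fully declared network (`pdl1_network()`, a YAML fixture) capturing
the PD-L1 regulation arms that the study reports as load-bearing:

* **ERK arm**: EGFR → RAS → RAF → MEK → ERK → AP1;
* **PI3K arm**: PIK3CA → AKT → MTOR → STAT3, with KEAP1 supporting the
  MTOR → STAT3 step;
* **Interferon-γ arm**: IFNG → IFNGR1 → STAT1 → IRF1;
* **Energy-sensing input**: STK11 → AMPK feeding MTOR;
* **TP53 arm**: wild-type TP53 inhibits all four PD-L1 transcription
  reactions; CDKN2A sustains TP53 turnover (its loss raises TP53-mediated
  inhibition) and supports AMPK activation.

AP1, STAT1, STAT3, and IRF1 converge on PD-L1 transcription, and the 23
non-PD-L1 readouts are modeled as lumped transcriptional targets of the
same four activation factors with varied gains — the study gives no
per-molecule pathway detail beyond PD-L1, so no finer structure is
justified.

Kinetics: activation steps are Michaelis–Menten productions
$V_\max S/(K_m + S)$ driven by the upstream species' *effective
concentration* (the driver is catalytic, not consumed); turnover steps are
mass action; modifiers scale rates by $A/(K_a + A)$ (activators) or
$K_a/(K_a + A)$ (inhibitors). Each species also has basal synthesis and
first-order degradation, so every baseline steady state is strictly
positive and percent changes are always defined.

**Mutation semantics.** Oncogene mutations are a gain of function at the
activity level and tumor-suppressor mutations a loss of function at the
activity level; copy-number events act at the expression level. The package
represents activity by a per-species multiplier applied wherever the
species *acts* (as a Michaelis–Menten driver or a modifier), while
mass-balance terms (synthesis, degradation, mass-action consumption) use
the raw concentration. This one mechanism covers all four effects —
`oncogene_gof` ×5, `tsg_lof` ×1/10 (defaults; magnitudes are unpublished
and chosen once for clearly separated effects), `amplification` ×5 on
synthesis, `deletion` zeroing synthesis — and acts correctly when the node
is an inhibitory modifier, which scaling a reaction's $V_\max$ would not.

**Steady states.** `simulate_steady_state()` integrates with the implicit
Radau method (stiff-capable, via deSolve) in chunks of 200 time units until
$\max_i |dX_i/dt| < 10^{-9}$ µM/time or the relative state change per chunk
falls below $10^{-8}$, up to a horizon of $10^5$; time units are arbitrary
since only steady states are read out. The packaged baseline converges with
residual ≈ $4 \times 10^{-13}$ and is frozen as a regression fixture;
halving tolerances moves steady states by less than $10^{-4}$ relative.

**Parameter choice.** Rate constants are not published. The packaged values
were chosen once so the network reproduces, with the default magnitudes,
the reported qualitative orderings of predicted PD-L1 change across KRAS
co-mutation subgroups — KRAS+TP53 (KP) > KRAS alone (K) > KRAS+STK11+KEAP1
(KL) > KRAS+CDKN2A/B (KC) — plus KRAS dose-response monotonicity and the
zero-perturbation identity. They are frozen in the YAML fixture and the
orderings are asserted by tests:

```{r orderings}
net <- pdl1_network()
pdl1_of <- function(muts) predict_profile(net, muts)$percent_changes[["PDL1"]]
gof <- function(g) mutation_profile(g, "oncogene_gof")
lof <- function(g) mutation_profile(g, "tsg_lof")
c(KP = pdl1_of(rbind(gof("RAS"), lof("TP53"))),
  K  = pdl1_of(gof("RAS")),
  KL = pdl1_of(rbind(gof("RAS"), lof("STK11"), lof("KEAP1"))),
  KC = pdl1_of(rbind(gof("RAS"), lof("CDKN2A"))))
```

No attempt is made to reproduce any reference patient's numeric profile
from their mutations: the generating network is proprietary, and the
packaged cohort is treated as given data.

## The synthetic-cohort generator

`generate_cohort()` exists so the classifier and concordance stages are
testable end to end with known ground truth. Two modes:

* **Parametric** (default): molecule percent changes are Gaussian. PD-L1,
  TGFB1, and IL6 share a latent factor with correlation 0.6 (these co-vary
  strongly in the reference cohort, and the correlation keeps step-3
  decisions non-trivial — an uncorrelated draw would make ISM excesses
  nearly independent of PD-L1). Chemokines are drawn iid and summarized
  with uniform weights.
* **Mechanistic**: each patient gets an independent Bernoulli draw over a
  lung-adenocarcinoma-flavored driver panel (RAS 0.35, TP53 0.40, PIK3CA
  0.20, STK11 0.20, RAF/EGFR 0.15, KEAP1/CDKN2A 0.15, MEK 0.10) and the
  profile comes from `predict_profile()` on the packaged network.

Each patient's **true label** is the decision tree applied to the noiseless
profile; observation noise (`noise_sd`, default 0) is added afterwards, and
the recorded clinical response is the true label flipped independently with
probability `label_flip_rate`. The flip rate is the generator's stand-in
for all unmodeled biology separating prediction from clinical outcome; its
preset value 4/29 ≈ 13.8% equals the reference cohort's observed
prediction/outcome mismatch fraction. `table1_preset()` additionally
matches every per-molecule mean and SD to the packaged cohort's columns and
sets the chemokine scale to 3× the DC-index SD (nine iid draws average to
one third the per-draw SD), so the uniform-weight index reproduces the
reference DC-index location and spread; the discovery split is 13/29.

Generation is deterministic given the config seed and restores the caller's
RNG state. Under the preset at n = 2000 the step-1 fraction lands within a
few points of the reference 9/29, and the expected match score converges to
$100(1 - \text{flip rate})$ — both asserted in tests.

```{r synthetic}
synth <- generate_cohort(table1_preset(n_patients = 200, seed = 42))
match_score(classify_cohort(synth$cohort)$traces$predicted,
            synth$cohort$clinical_response)
```

What the generator does *not* emulate: real cohorts are not Gaussian (the
reference PD-L1 column is right-skewed with values up to 185%), molecules
beyond the PD-L1/TGFB1/IL6 trio are drawn independently although biology
correlates them, and label flips are independent of the profile whereas
real mismatches plausibly concentrate near decision boundaries. Passing
recovery tests therefore demonstrates correctness of the pipeline's
plumbing and statistics, not clinical validity on real data.

## Numerical and degenerate-input choices

* Percent changes require a strictly positive baseline; a nonpositive
  control is a domain error, never an NA.
* Chemokine weight vectors are renormalized when their sum deviates from 1
  by at most $10^{-6}$ and rejected beyond that.
* Fisher's two-sided sum includes tables whose point probability is within
  relative $10^{-7}$ of the observed one, absorbing floating-point ties;
  degenerate margins return p = 1 with a flag. The implementation is checked
  against exhaustive enumeration and `stats::fisher.test`.
* The loader accepts Unicode minus signs and thin spaces in numeric cells
  (the reference table prints both) and normalizes molecule-name synonyms
  (`CX3CL` → `CX3CL1`, `PD-L1` → `PDL1`).
* Cohort files are written at full double precision, so write/read round
  trips are exact.
* The ODE right-hand side clamps negative excursions at 0 before evaluating
  rate laws; integration that drifts below −10⁻⁸ µM aborts with an error.

## Problem sizes used in the test suite

The suite runs the tree/oracle equivalence on 10,000 randomized profiles,
Fisher enumeration cross-checks on all 2×2 tables with totals up to 8 plus
300 randomized tables with margins up to 30, label-recovery at n = 1000,
preset calibration at n = 2000, and mechanistic generation at n = 8
(each mechanistic patient costs one stiff ODE solve). These sizes give
stable assertions at comfortably sub-minute runtimes per file.

## Known limitations

* The reduced network is a qualitative stand-in: it reproduces reported
  orderings and directions, not any quantitative patient profile.
* The published per-chemokine weights being unavailable, synthetic DC
  indices are uniform-weight; classification of the packaged cohort is
  unaffected because its published index values are used as-is.
* The tree's thresholds are taken as given; the package deliberately
  provides no threshold fitting (re-running the tree at alternative cutoffs
  is supported for sensitivity reporting).
* Training/Test re-partition match scores reported alongside the
  discovery/validation analysis are not reproducible — the partition
  membership was never published — and are out of scope; user-supplied
  partitions can be analyzed generically by relabeling the `dataset`
  column.
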