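---
title: "Scanning marker pairs for statistical epistasis: methods and design"
author: "episcape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scanning marker pairs for statistical epistasis: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(episcape)
```

## The problem

Complex disorders such as major depressive disorder show substantial
heritability but few replicated single-locus effects, which motivates
searching for *statistical epistasis*: pairs of markers whose joint effect
departs from what their single-locus effects predict. "Departs from" has no
unique meaning — it depends on the scale on which single-locus effects are
combined — so this package implements three complementary definitions and
the machinery to scan candidate-gene panels with all of them:

* **additive scale** — departure from additivity of excess risks, measured
  by the relative excess risk due to interaction (RERI) and the
  attributable proportion due to interaction (AP);
* **multiplicative scale** — the product-term coefficient of a logistic
  model with two binary exposures;
* **model-free** — multifactor dimensionality reduction (MDR), which labels
  joint-genotype cells high or low risk and scores the induced classifier.

The surrounding machinery (single-marker trend tests, marker
prioritisation, permutation-based family-wise correction, LD pruning of top
lists, classifier metrics, cross-method correlation) reproduces a complete
case-control interaction-analysis pipeline, and a genotype simulator with
known two-locus effects makes every stage testable end to end.

## Genotype codings and the joint-exposure table

Genotypes are stored as minor-allele dosages 0/1/2; the minor allele is
determined per marker from the pooled allele frequency, which makes all
downstream statistics orientation-invariant (a property the test suite
checks). A marker is collapsed to a binary exposure either **dominantly**
(carrier: dosage ≥ 1) or **recessively** (minor-allele homozygote:
dosage = 2). For a pair of markers the analysis unit is the 2 × 4 table of
case/control counts over joint-exposure cells 00, 01, 10, 11 (marker 1's
exposure first). Samples missing either genotype are dropped per pair
(complete-case), which matches how per-pair totals behave in published
candidate-gene tables.

## Preventive-factor recoding

RERI and AP presume that each single exposure is risk-conferring relative
to the reference cell. When an exposure is protective the four cells are
relabelled by one of four exposure-inverting permutations (identity, invert
marker 1, swap markers with one exposure inverted, invert both). The
selection rule is: **make the cell with the lowest case:control odds the
new reference 00**, with ties broken in a fixed preference order (keep 00,
then prefer old 10, 01, 11). This guarantees all three odds ratios against
the reference are at least 1, is deterministic, and — unlike "first scheme
with OR01, OR10 ≥ 1" — is uniquely defined when several schemes would
satisfy the weaker condition. Counts never change; only labels move, and
the applied scheme is recorded with the result. Recoding is applied for
additive-scale statistics only: the multiplicative interaction coefficient
and its Wald test are invariant to exposure orientation, so recoding there
would only relabel the reported direction.

## Additive-scale statistics

With odds ratios OR01, OR10, OR11 taken against the (recoded) reference
cell,

RERI = OR11 − OR01 − OR10 + 1, AP = RERI / OR11.

On an all-positive table these odds ratios are the maximum-likelihood
estimates of the saturated logistic model, so the package computes them in
closed form and the test suite verifies equality with `glm()` fits to six
significant digits. The variance of AP uses the delta method on the three
log-odds-ratio coefficients (the standard Hosmer–Lemeshow formulation),
with the saturated-model covariance assembled from reciprocal cell counts;
the 95% interval is AP ± 1.96·se and the two-sided P value comes from
z = AP/se. When a cell is empty the point estimates are reported as they
are (possibly infinite) and the variance — including the gradient — is
evaluated at 0.5-continuity-corrected counts, flagged `small_cell`.

AP is never truncated. Values below −1 occur in real scans whenever the
doubly-exposed odds ratio in the denominator is small; `ap_diagnostics()`
tabulates AP against the minimum cell count and the single-exposure odds
ratios to make that pathology visible, and the package's position is that
such values signal qualitative protection whose magnitude should not be
interpreted.

## Multiplicative-scale statistics

`multiplicative_fit()` fits the saturated logistic model
status ~ expA + expB + expA:expB on the grouped counts and reports
exp(β3) — equal to OR11/(OR01·OR10) — with a Wald interval whose standard
error is the square root of the sum of reciprocals of the eight cell
counts. The Wald convention (rather than a likelihood-ratio test) is used
because it reproduces published per-pair P values exactly from the printed
counts. Empty cells switch the fit to a flagged closed-form
continuity-corrected path.

## MDR

For a marker pair the joint genotype grid is 4 × 4: dosages 0/1/2 plus a
missing category per marker, so no samples are dropped. A cell is labelled
high-risk when its training case:control ratio is at least the training-set
ratio T; non-empty cells without controls are high (ratio +∞), entirely
empty cells low. The induced binary classifier is scored by balanced
accuracy BA = (TPR + 1 − FPR)/2; `mdr_evaluate()` reports full-data BA,
the high/low classification counts, the high/low odds ratio with a Wald
interval, a Pearson chi-square P value, and the mean testing BA over
stratified 10-fold cross-validation (folds depend only on a seed).
`mdr_scan()` evaluates every pair (vectorised via level-indicator
cross-products), ranks by testing BA with full-data BA and then
lexicographic order as tie-breaks, and reports the cross-validation
consistency CVC — in how many folds a pair attains the best *training* BA.
Reported table metrics use full data, because published MDR tables are
exactly reproducible from full-data counts; both BA variants are exposed.

## Classifier metrics

* **AUC** is computed by category concordance: the four exposure cells are
  ordered by case:control odds and AUC is the probability a random case
  outranks a random control, ties counting one half. This equals the
  individual-level Mann–Whitney statistic exactly (tested against a
  brute-force double loop) and reproduces published values, unlike a
  fitted-probability ROC.
* **Sensitivity/specificity** are case mass in high-risk categories and
  control mass in low-risk categories.
* **Attributable fraction** uses the Miettinen case-load form
  AF = Σ pc·(OR − 1)/OR over non-reference categories (equivalently
  1 − Σ pc/OR). Published per-pair "PAF" values in this literature cluster
  near the disease prevalence and are not reproduced by standard formulas
  from the printed counts, so the package implements and labels the
  documented Miettinen form rather than guessing an unstated convention.

## Marker prioritisation and the scan

Exhaustive regression scans over thousands of markers are expensive, so the
pipeline seeds the regression scans with the union of (A) markers with a
Cochran–Armitage trend P below a threshold (default 0.05) and (B) the top
markers by a ReliefF relevance score among the remainder — ReliefF rewards
markers whose genotype differences separate cases from controls locally,
so it can surface markers that act only through dependencies. The trend
test uses scores 0/1/2 via `prop.trend.test`; the suite checks it against
an explicit summation formula. The seed-against-all stream reports both the
raw evaluation count (|seeds| × |markers|, the bookkeeping figure such
designs quote) and the deduplicated unordered pair count actually ranked.

Two-cohort heterogeneity assessment is available via `meta_analyze()`:
Woolf's inverse-variance Q test decides between a Mantel–Haenszel
fixed-effect and a DerSimonian–Laird random-effects pooled odds ratio
(both computed through metafor), with a Wald pooled P.

## Permutation-based family-wise correction

`permute_fwer()` implements the max-statistic method: case/control labels
are permuted B times, the scan is re-run, and the best statistic of each
permuted scan (|z| for the regressions, testing BA for MDR) forms the null
distribution of the study-wide maximum. The adjusted P of an observed
record is (1 + #{permutation best ≥ observed})/(B + 1) — the add-one
estimator avoids zero P values — and the family-wise 5% threshold is the
95th percentile of the permutation-best distribution. Calibration is
verified on null data in the test suite.

## LD pruning of top lists

Top-k tables are pruned greedily from the best rank using composite
(dosage-correlation) r², the appropriate measure for unphased data. The
default redundancy rule is pair-level: a candidate is dropped only when
*both* of its markers are in LD (r² above the threshold; an identical
marker counts) with the two markers of an already-kept pair under some
alignment. This keeps pairs that share one marker but differ in the other —
the behaviour seen in published top-interaction tables, where several
retained pairs share a hub marker while the non-shared markers are in weak
LD. A stricter marker-level rule (`rule = "marker"`) is available. After
pruning, no kept pair duplicates another at the threshold, a property the
suite checks on simulated LD blocks.

## The simulator

`simulate_case_control()` draws population genotypes under Hardy–Weinberg
equilibrium at per-marker minor-allele frequencies uniform over
`maf_range`, assigns disease by the configured risk model, and collects
exactly `n_cases` cases and `n_controls` controls by rejection sampling —
matching the fixed-quota case-control design rather than
prevalence-weighted sampling. Effects:

* `effect_main` / `effect_multiplicative`: contributions on the logistic
  scale (the generative counterpart of the multiplicative model);
* `effect_additive`: exposure-category risks on the risk-ratio scale —
  R01 = R00·RR01, R10 = R00·RR10, R11 = R00·(RR01 + RR10 − 1 + RERI) —
  anchored at the baseline prevalence, because AP is defined on that scale;
  a target AP is converted to RERI via AP·(RR01 + RR10 − 1)/(1 − AP);
* `effect_grid`: an explicit 3 × 3 penetrance grid, e.g. XOR-style purely
  epistatic patterns with null margins.

Defaults mirror a realistic candidate-gene study: 1,732 cases, 1,783
controls, 3,704 markers in 63 gene groups, baseline prevalence 0.15 (the
high-prevalence regime of major depression), 0.1% missing genotypes, MAFs
in (0.05, 0.5) as typical for common-variant panels. Null markers are
independent unless LD blocks are requested (`ld_blocks` copies a block's
lead marker with a configurable probability), so LD pruning stays testable
while the default model stays simple.

One subtlety matters for validation: with a 15% baseline prevalence the
odds ratios estimated from case-control data are inflated relative to the
risk-ratio scale on which additive effects are specified — precisely the
inflation discussed in the epidemiological literature on AP from odds
ratios. The simulator therefore also reports the *exact odds-scale* OR01,
OR10, OR11, RERI and AP implied by the generating risks under case-control
sampling (computable analytically from the cell probabilities), and bias
and confidence-interval coverage are assessed against that implied
estimand, not against the risk-scale target. Coverage of the delta-method
AP interval on simulated additive pairs (n = 5,000/5,000, 500 replicates)
falls in the nominal band.

What the simulator does not emulate: realistic haplotype/LD structure from
reference panels, population stratification, genotyping batch effects, and
covariates. Passing tests therefore demonstrate correctness of the
statistics under clean sampling assumptions, not robustness to confounding
— the single-marker module deliberately fits unadjusted models.

## Numerical choices

* Continuity corrections: 0.5 added to all cells of a table containing a
  zero, for variance computation (additive), the whole fallback fit
  (multiplicative), odds-ratio intervals (MDR, meta-analysis); always
  flagged.
* Tie-breaks: recoding reference preference (00, 10, 01, 11); MDR ranking
  by testing BA, then full-data BA, then lexicographic pair; CVC best-fold
  ties to the first (lexicographic) pair; tied category odds contribute ½
  to AUC.
* Seeds: fold assignment, permutations, ReliefF sampling and the simulator
  all take explicit seeds; every pipeline output is a pure function of
  (input, configuration, seed), verified byte-for-byte in the suite.
* Degenerate inputs: monomorphic markers are retained but flagged; tables
  with an empty case or control stratum are marked degenerate and refuse
  the interaction fits; constant-dosage markers yield an undefined-LD
  signal (`NA`) distinct from r² = 0.

Problem sizes in the test suite are chosen for a laptop-class run: null
calibration at 2,000 replicates of 1,000/1,000, coverage at 500 replicates
of 5,000/5,000, MDR detection at 50 runs of 32 markers × 2,000 samples,
permutation calibration at 100 datasets × 200 permutations. These sizes
give binomial Monte-Carlo envelopes tight enough to detect miscalibration
of a few percentage points.

## Known limitations

* Single-marker and interaction models are unadjusted (no principal
  components or other covariates); applying the package to structured
  populations will confound both the scans and the prioritisation.
* The additive P value convention (z on AP) is one of several in use;
  published per-pair additive P values are reproduced closely but not
  bit-exactly, and the package documents rather than chases the original
  convention.
* The attributable-fraction column is the Miettinen case-load form, which
  need not match "PAF" columns computed under other conventions.
* MDR is implemented for 2-way scans with a loop-based 3-way option;
  higher orders and permutation distributions specific to MDR software
  GUIs are out of scope.
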