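---
title: "Predicting preeclampsia from cfDNA promoter coverage: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting preeclampsia from cfDNA promoter coverage: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cfpe)
```

## The scientific problem

Preeclampsia (PE) is a hypertensive pregnancy complication; its early-onset
form (diagnosed before 34 weeks of gestation) is the one most worth
predicting early, because low-dose aspirin started in the first trimester
reduces risk. Non-invasive prenatal testing (NIPT) already sequences
maternal plasma cell-free DNA (cfDNA) at very low coverage (~0.1X) in
millions of pregnancies to screen for fetal aneuploidy. About 10–15% of
that cfDNA comes from placental trophoblasts, and transcriptionally active
promoters are nucleosome-depleted in the placenta: DNA from active
promoters is degraded preferentially, so *lower* cfDNA coverage over a
promoter signals higher placental expression of that gene. `cfpe`
implements a complete, testable pipeline that turns this signal — plus a
handful of routinely collected clinical risk factors — into early- and
late-onset PE risk classifiers, with the evaluation protocol (bootstrap
AUC confidence intervals, fixed-specificity operating points, DeLong
comparisons) needed to judge them across hospitals.

## The coverage statistic

For each transcript, the promoter window is the 2 kb region centered on
the transcription start site (TSS), `[tss - 1000, tss + 1000)` in 0-based
half-open coordinates. Per sample, the promoter coverage is the RPKM-scaled
read count

$$\mathrm{coverage}_i \;=\; \frac{n_i \times 10^9}{N \times 2000},$$

where $n_i$ is the number of retained reads assigned to window $i$ and $N$
the sample's total retained mapped reads. Retained means mapped, primary,
non-supplementary, non-duplicate. A read is assigned to a window by its
leftmost aligned base (`count_mode = "start"`); windows are 57 times the
read length, so this differs negligibly from any-overlap counting, which
is available as `count_mode = "overlap"` (a read spanning two windows then
counts in both — no fractional assignment).

Coverages are then rescaled to **multiples of the median (MoM)** — the
standard normalization of prenatal screening analytes: each value is
divided by the median coverage of the *control* samples of the same
dataset (hospital) at that promoter. MoM cancels any per-dataset
multiplicative depth difference exactly, which is the property that makes
multi-hospital pooling defensible; the package tests assert this
cancellation to 1e-12 and that the per-dataset control median of MoM is
exactly 1 (exact for odd control counts). Promoters whose control median
is zero in a dataset are *undefined* there — excluded downstream, never
pseudocounted or set to infinity, because at 0.1X a pseudocount would
distort the MoM = 1 anchor for sparse promoters.

## Sample QC

Samples are screened once, before any train/validation split, by PCA on
the coverage matrix (columns mean-centered, not variance-scaled — scaling
is available behind a flag but coverage is already on a common scale). A
sample is excluded when its score on either of the first two principal
components lies more than 3 standard deviations from that component's
mean. The filter is deliberately single-pass: re-running it on the
retained set could exclude more samples, and the reference protocol
filtered once. With identical samples the score standard deviation is 0
and nobody is excluded (0 ≤ 0). Sign indeterminacy of the SVD is fixed by
making each component's largest-magnitude loading positive, so reruns are
bit-identical.

## Stability selection of differential promoters

A promoter is a candidate biomarker for a class (early- or late-onset)
only if it is *stably* differential: the two-sided Wilcoxon rank-sum test
comparing cases with controls is repeated on `n_iter = 1000` random
subsamples containing 70% of the discovery samples, and the promoter is
selected when

1. the upper limit of the 95% CI of its p-values — read as the empirical
   97.5th percentile of the 1,000 p-values (distribution-free; a
   mean ± 1.96·SE variant would assume approximate normality of p-values,
   which holds for none of the interesting promoters) — is below 0.05,
   **and**
2. the sign of (case median − control median) is identical in every
   iteration with a nonzero difference. Iterations with a zero difference
   are ignored, but a promoter with more than 10% zero-difference
   iterations is demoted to direction `"mixed"` and never selected — the
   strictest reading of "same trend" that tolerates sparse-count ties.

Subsampling is stratified by case/control status (`floor(0.7 n)` per
group): with as few as ~50 early-onset cases in a training hospital,
unstratified draws would occasionally leave near-empty case groups.
Unstratified draws are available behind a flag. No multiple-testing
correction is applied across promoters — the stability criterion itself is
the error control, and on fully null synthetic cohorts the suite verifies
a selected fraction ≤ 1%, far below the nominal 5% of a single test.

The Wilcoxon implementation follows the classical two-regime rule: exact
enumeration when `min(n, m) ≤ 10` with no ties, otherwise the normal
approximation with tie-corrected variance and 0.5 continuity correction
(this is also `stats::wilcox.test`'s behavior, against which the
vectorized inner loop is tested). A numerical note: the worst-case
disagreement between the approximate and exact two-sided p-value over
*all* tie-free configurations is ≤ 0.0173 once both groups have ≥ 5
observations, but reaches 0.0305 for 4-vs-4 — the suite's
oracle-agreement bound of 0.02 is therefore asserted for group sizes 5–8,
where it is a theorem rather than seed luck.

Clinical covariates are screened per class with the Mann–Whitney U-test
(age, height, weight, BMI) and Fisher's exact test (parity ≥ 1,
gravidity ≥ 2, past-medical-history score ≥ 1, IVF conception), with
NS/\*/\*\*/\*\*\* marks at 0.05/0.01/0.001.

## Feature vectors and classifiers

Both classifiers share five clinical encodings: maternal age and BMI as
MoM against the per-dataset control medians (mirroring the cfDNA
convention; the reference protocol does not say over whom its clinical
medians were taken, so the control-median choice is applied uniformly),
parity as a count, the past-medical-history score as the 0–4 sum of
chronic hypertension, prior PE, SLE and antiphospholipid syndrome flags,
and conception encoded 1 for IVF, 0 for natural.

- **Early-onset (C_EPE)**: the clinical encodings plus the promoter MoM
  coverages of eight profile genes (FOSL2, CAMKK2, CCND1, ITPR1, PRKACB,
  WNT7B, CACNB2, NRF1) — 13 features — fed to a logistic regression on
  z-scored features, fitted by maximum likelihood (`stats::glm`); with 13
  features and hundreds of training samples an explicit penalty adds
  nothing, and separation warnings are benign saturations.
- **Late-onset (C_LPE)**: the clinical encodings plus the single ratio
  MoM(FLT3LG)/MoM(EGF) — 6 features — fed to a 500-tree random forest
  (Gini impurity, `floor(sqrt(p))` variables per split, no depth cap,
  fixed seed). The ratio's numerator/denominator order is fixed and no
  log transform is applied (none is part of the reference definition);
  samples with a zero or undefined denominator are excluded and counted.

Both model kinds work for both contexts; the defaults follow the
reference pairing. Feature schemas are frozen per context and carried as
a hash that prediction verifies, so a model can never silently consume
reordered or renamed features. Missing values are handled by complete-case
analysis only — the cohort definition requires complete clinical records.

Training fixes an operating threshold: the smallest score cutoff whose
training specificity is ≥ 0.90. Evaluation re-anchors the threshold on
each evaluated dataset by default (`protocol = "per-dataset"`), because
multi-hospital score distributions shift and the reference results report
specificity pinned at 0.90–0.91 in every dataset; transferring the
training threshold verbatim is available as `protocol = "fixed"`.

## Evaluation

AUC is the tie-aware Mann–Whitney statistic divided by
$n_\text{case} n_\text{control}$. Its 95% CI is a percentile bootstrap over
1,000 resamples of the pooled sample set at original size; resamples that
lose a class are redrawn and counted. Operating-point metrics (accuracy,
sensitivity, specificity, PPV, NPV) all come from the single confusion
matrix at the chosen threshold. Correlated AUCs on the same samples are
compared with DeLong's test in the placement-value formulation; when the
variance of the AUC difference is exactly zero the comparison is flagged
degenerate — p = 1 if the AUCs agree (identical classifiers), p = 0 if
they differ (perfectly separated disagreement, where the z statistic
diverges). The suite checks the AUC against an all-pairs $O(n^2)$ oracle,
the threshold against an exhaustive sweep, bootstrap coverage on a known
AUC = 0.75 population (coverage within 0.90–0.99 at n = 200/200), the
DeLong p against `pROC`, and its type-I error at n = 100/100 (0.03–0.07 at
α = 0.05).

## The synthetic cohort generator

Real cohort data are controlled-access; the generator produces cohorts
with exactly the statistical structure the pipeline assumes, plus a truth
ledger for verification. Per sample, a read budget is drawn around
`mean_reads_per_sample`; a fraction `window_weight` of reads is attracted
to promoters proportionally to per-promoter gamma-distributed weights;
case samples multiply their class's planted promoters' weights by a fold
change; counts are Poisson (optionally negative binomial with
`variance = mu + dispersion mu^2`); background reads fall uniformly in
inter-window gaps, and per-dataset depth differences are a pure
multiplicative batch factor — deliberately so, because MoM's batch
cancellation is a property under test, not an assumption. Read-level
output (35 bp single-end SAM/BED, convertible to BAM) and matrix-level
output share the same expectation model; the suite verifies both the
Poisson moments and the convergence of case/control count ratios to the
planted fold.

Reference conditions, chosen once: four hospital datasets at study-scale
sizes (controls 276/528/406/779, early-onset 54/30/16/40, late-onset
145/160/115/160), 500 promoters, 1e4 mapped reads per sample with 30% in
windows — about 6 expected reads per 2 kb window, the in-window depth of
0.1X sequencing with 35 bp reads. Clinical covariates are log-normal (age,
BMI), normal (height), and Bernoulli (parity, history flags, IVF) with
class-conditional parameters digitized from the reference cohort's
training-set medians and IQRs; weight is derived as BMI × height² so the
three are always consistent; late-onset parameters, not printed in the
reference's main text, are milder versions of the early-onset shifts.
Profile genes are bound to promoters at the top-quartile boundary of the
baseline-rate distribution: such promoters always have a nonzero control
median even at sparse depth, yet carry too little absolute coverage for
the planted effects to dominate the cohort's principal components (bound
to the very top promoters, a planted fold of 1.5 made cases separate in PC
space and the QC filter excluded them wholesale — a failure mode real
cohorts do not show).

What the generator does **not** emulate: sequencing error, mapping
ambiguity, GC and mappability bias, fetal-fraction variation, fragment
length distributions (the reference data are single-end), promoter-specific
batch effects, and correlated promoter co-regulation. Passing tests
therefore demonstrate the pipeline's correctness and its operating
characteristics under the declared model — not clinical performance on
real plasma.

## Problem sizes and seeded regressions

The test suite scales simulations to desk size as its own design choice:
stability-selection operating characteristics use 200 of the protocol's
1,000 iterations (the 97.5th-percentile criterion stabilizes well before
200), null and power cohorts use 500 promoters at n = 100/100, bootstrap
coverage uses 200 Monte-Carlo replicates, and the DeLong size check 1,000
replicates. The end-to-end "combination helps" regression — combined
features ≥ max(clinical-only, cfDNA-only) AUC on every validation dataset
— is asserted on a seeded 4-dataset cohort calibrated to the operating
regime the reference reports (cfDNA-only validation AUCs well below
ceiling, comparable to clinical-only: fold 1.3 at 3,000 reads per
sample). It is a regression test of a qualitative claim at a fixed seed,
not a theorem: with either source near AUC = 1, combining can lose a few
thousandths on a finite sample, which is expected behavior, not a defect.

## Known limitations

- The "primary TSS" selection of the reference (one TSS per gene) is
  detailed only in its supplementary material; the package defaults to
  transcript-level windows and offers a per-gene mode (first-listed
  transcript) instead of guessing.
- Random forests serialize to JSON as tree dumps for provenance, but are
  not restored from JSON; reproduction is by retraining under the stored
  seed.
- The logistic model is unpenalized; for feature sets much wider than 13
  promoters a penalized fit (`glmnet`) would be the right extension.
- PCA QC excludes a slightly larger fraction of synthetic samples than
  the reference excluded of real samples (count RPKM PC scores are
  heavier-tailed than Gaussian); the threshold stays at the protocol's
  3 sd rather than being tuned.
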