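---
title: "Benchmarking merging and integration strategies for two-batch LC-MS metabolomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking merging and integration strategies for two-batch LC-MS metabolomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Large clinical metabolomics cohorts are acquired in batches, often months
apart. Given two LC-MS experiments measuring the same case/control contrast
(here: hepatocellular carcinoma vs. cirrhosis serum), the analyst must choose
among:

* **SiE1 / SiE2** — analyse each experiment on its own;
* **ReIn** (results integration) — run each experiment's pipeline separately
  and combine the *results*;
* **DiMe** (direct data merging) — match the two experiments' features by
  m/z, concatenate all samples into one table, and analyse jointly.

`metastrat` implements all four strategies over aligned peak tables
(features × samples with per-feature m/z and retention time) and scores each
under three mutually independent criteria:

1. **Classification capacity** — t-test feature selection, an RBF-kernel SVM
   tuned on a test split, SEN/SPE/ACC/MCC and rank-based AUC on an untouched
   independent split;
2. **Robustness** — ten stratified half-samplings, a Student's-t marker list
   from each, all 45 pairwise *overlap* values
   \(2|a \cap b| / (|a| + |b|)\), their median, and the co-identification
   profile (markers found by all 10 / ≥9 / … / ≥6 lists, as a percentage of
   the union);
3. **False-discovery control** — PLS-DA markers (VIP > 1 and p < 0.05)
   annotated against a metabolite library at 20 ppm, scored by the
   *enrichment factor*
   \(\mathrm{EF} = \frac{t_{id}/n_{id}}{t_{det}/n_{det}}\), the true-marker
   rate among identified metabolites relative to random selection from the
   detected universe (EF = 1 ⇔ no better than random).

## Worked example

```{r, eval = FALSE}
library(metastrat)
pair <- generate_pair(synthetic_config(seed = 42))
cfg  <- run_config(seed = 7)
cmp  <- compare_strategies(pair$exp1, pair$exp2, cfg,
                           pair$library, pair$truth$true_metabolite_ids)
cmp
write_comparison(cmp, "report/")
```

The comparison reproduces, on synthetic data, the qualitative behaviour the
strategy debate is about: DiMe gains classification accuracy and marker
robustness from the doubled sample size, while ReIn's intersection of
per-experiment results is the most conservative against false discoveries
(highest EF), at the price of identifying fewer metabolites.

## The pipeline and its parameters

| parameter | default | meaning |
|---|---|---|
| `tol_value`/`tol_unit` | 0.05 Da | m/z window for cross-batch feature matching |
| `k` | 10 | neighbours for KNN imputation |
| `alpha` | 0.05 | significance threshold, used throughout, uncorrected |
| `vip_threshold` | 1 | VIP cutoff in the PLS-DA conjunction rule |
| `n_components` | 2 | PLS components behind the VIP scores |
| `annotation_ppm` | 20 | metabolite annotation window |
| `split` | 0.6/0.2/0.2 | train/test/independent fractions, stratified |
| `n_iter` | 10 | half-samplings for the robustness criterion |

**Merging.** Features are matched greedily one-to-one by smallest |Δm/z|
within the tolerance; RT is deliberately not used. The literature this
design follows prints a tolerance of 0.05 *ppm*, which cannot be meant
literally — at m/z 500 that is 2.5×10⁻⁵ Da, an order of magnitude below
QTOF mass accuracy — so the shipped default is 0.05 Da, with
`tol_unit = "ppm"` available to reproduce the printed value literally.
Merged feature m/z is the intensity-weighted mean of the pair, computed in
convex-combination form so identical inputs stay bit-identical. Pretreatment
is applied to the *merged* table, not per batch, mirroring the DiMe workflow
order; no explicit batch correction is applied because MSTUS normalization
already cancels any per-sample multiplicative (location-on-log) batch shift
exactly.

**Pretreatment.** KNN imputation first, MSTUS second. Neighbour distances
are Euclidean over mutually observed samples, RMS-scaled so that neighbours
with different overlap sizes are comparable; a neighbour must share ≥3
observed samples (relaxed to ≥1 when nothing qualifies, before the
feature-mean fallback). `k = 10` is the common omics default; the source
design never states K, the metric, or the denominator convention, so all
three are configurable. "Total useful signal" is read as the features
observed in *every* sample before imputation; if no feature is complete the
package warns and falls back to total-signal normalization.

**Markers.** The t-test is the pooled-variance Student form, read literally
from the method's name (Welch is not used); no multiplicity correction
anywhere, because the benchmark's published marker counts are raw p < 0.05
counts. The p-value paired with VIP in the conjunction rule is the
univariate t-test p. VIP comes from a NIPALS PLS1 fit on autoscaled
features with the standard normalised-weight formula, so
\(\sum_j \mathrm{VIP}_j^2 = P\) exactly — an identity the tests assert.
Annotation uses a single ±H adduct by ionisation mode; the synthetic
library is generated consistently with that model.

**Classification.** Split fractions default to 60/20/20 stratified (the
source is silent). The MCC is computed with the square root in the
denominator; the printed form of the formula this follows omits it, but its
published values lie in [−1, 1], which requires the root. The SVM is an
in-package simplified-SMO C-SVC with RBF kernel (no SVM package exists in
the supported dependency set); cost and gamma are picked on the test split
over a small fixed lattice, the final model is refit on train+test, and the
independent split is used once, for metrics only — a leakage test asserts
that permuting its labels cannot change the fitted model.

**ReIn integration.** The published description ("collectively considered")
is underspecified. The package intersects the two experiments' annotated
universes and identified metabolite sets for the EF (intersection, not
union, is the only simple rule consistent with ReIn identified counts
falling far below both single-experiment counts in the published tables),
averages the two experiments' classification metric vectors, and averages
overlap values pairwise across iterations (which reproduces the published
convention of non-integer per-iteration marker counts). Under this
definition `ReIn(A, A) ≡ SiE(A)` exactly, which the test suite asserts.

**Robustness.** Half-sampling uses `floor(n_g/2)` per group ("50%" is
ambiguous for odd counts). Overlap distributions are compared with a
one-sided Wilcoxon rank-sum test; the test behind the published p-values is
unnamed, and rank-sum is the natural nonparametric choice for 45 unpaired
overlap values.

## What the synthetic generator emulates — and what it does not

`generate_pair()` produces two experiments with log-normal intensities
(feature baselines N(10, 1.5), within-group SD 0.6 on the log scale),
planted true markers shifted by `effect_size` log-SDs in cases with the
*same sign in both batches*, a batch location shift (multiplicative on the
natural scale) plus a dispersion factor in experiment 2, jittered m/z on
shared features, private features per batch, and intensity-dependent
missingness. Defaults are fixed once to the benchmark regime the package
targets: 20 cases / 25 controls per experiment (the smaller published
benchmark pair), 600 shared + 300 private features, 12 true markers (the
size of the curated serum marker panel for HCC vs. cirrhosis), effect size
1.0 log-SD — chosen because it reproduces the published degree of
marker-list instability (median overlaps around 0.15–0.40) rather than a
trivially easy or impossible problem — batch shift 0.5 log units, scale
factor 1.2, 20% missingness with half the budget as low-intensity
censoring, and Poisson(40) decoy library records per feature inside the
20 ppm window so that annotation is one-to-many at the realistic
tens-of-metabolites-per-peak rate.

Missingness is concentrated: half of the features (`complete_fraction`) are
never missing, emulating the well-detected core of an aligned peak table;
the remainder carry the whole missingness budget, split between censoring
of the lowest-intensity quantile (`mnar_weight`) and completely-random
dropout. A purely i.i.d. per-cell model would leave *no* complete feature
in realistic sample sizes and hence no MSTUS denominator.

The generator does **not** simulate chromatography, isotope patterns,
adduct networks, retention-time drift, or correlated feature blocks. A
green test on synthetic data therefore establishes the *procedural*
correctness and the direction of strategy differences under the stated
statistical model — not performance on any particular real cohort.

## Numerical choices and degenerate inputs

* Zero-variance features: p = 1 by convention in the t-test (logged);
  unit-variance substitution during PLS autoscaling.
* Two empty marker lists: overlap 0 by convention.
* EF with ≤1 identified true marker is flagged `low_support` (the published
  tables show a single-true-marker ReIn row whose EF is numerically
  unstable in exactly this way); a truth set disjoint from the universe
  yields `NA` with `ef_undefined = TRUE`, never silently 0.
* Matching ties (equal |Δm/z|) break toward the lower-m/z pair; the greedy
  matcher is symmetric in its arguments, asserted property-style.
* All randomness flows from explicit seeds; one master seed fans out to
  stage seeds through a fixed linear-congruential derivation kept below
  2³¹, and reports embed config + seeds sufficient to re-run bit-identically.

## Known limitations

* Exactly two experiments; no >2-batch designs or meta-analytic pooling.
* No RT-based alignment and no intensity batch correction beyond MSTUS.
* The SMO SVM is adequate for benchmark-sized cohorts (hundreds of
  samples), not for thousands.
* ReIn's classification "integration" is metric averaging; the published
  account leaves the operator undefined, and no simple rule reproduces all
  of its printed classification rows, so this choice is the documented
  convention rather than a validated reconstruction.
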