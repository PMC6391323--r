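# metastrat

Strategy benchmarking for **multi-batch LC-MS metabolomics**. When the same
case/control contrast (e.g. hepatocellular carcinoma vs. liver cirrhosis
serum) has been measured in two experiments, the analyst can

* analyse each experiment alone (**SiE1**, **SiE2**),
* run both pipelines separately and integrate the results (**ReIn**), or
* merge the two peak tables by m/z into one large dataset first (**DiMe**).

`metastrat` implements all four strategies end-to-end over aligned peak
tables and scores each on three independent criteria:

* **Classification capacity** — Student's-t feature selection, RBF-SVM
  tuned on a test split, and SEN / SPE / ACC / MCC / AUC on a held-out
  independent split:
  `SEN = TP/(TP+FN)`, `SPE = TN/(TN+FP)`, `ACC = (TP+TN)/N`,
  `MCC = (TP·TN − FP·FN)/√((TP+FN)(TP+FP)(TN+FP)(TN+FN))`,
  AUC by the Mann–Whitney rank formulation.
* **Robustness** — 10 stratified half-samplings, a t-test marker list from
  each, all 45 pairwise *overlap* values `2|a∩b|/(|a|+|b|)`, their median,
  and the co-identification profile (markers found by all 10, ≥9, …, ≥6
  lists as a percentage of the union).
* **False-discovery control** — PLS-DA markers (VIP > 1 and p < 0.05)
  annotated at 20 ppm against a metabolite library and scored by the
  **enrichment factor** `EF = (t_id/n_id)/(t_det/n_det)`, the true-marker
  rate among identified metabolites relative to random selection from the
  detected universe; EF = 1 means no better than random.

A fully seeded synthetic generator (`generate_pair()`) produces paired
experiments with planted differential metabolites, batch location/scale
shifts, m/z jitter, intensity-dependent missingness, and a decoy-rich
reference library, so the whole pipeline is testable offline. The packaged
true-marker fixture is the curated panel of twelve experimentally validated
serum metabolites discriminating HCC from cirrhosis (`load_true_markers()`).

## Worked example

```r
library(metastrat)
pair <- generate_pair(synthetic_config(seed = 42))   # two batches + library + truth
cfg  <- run_config(seed = 7)                         # all pipeline thresholds
cmp  <- compare_strategies(pair$exp1, pair$exp2, cfg,
                           pair$library, pair$truth$true_metabolite_ids)
print(cmp)
```

```
Strategy comparison (seed 7 )

Classification:
  strategy   ACC   SEN SPE   MCC   AUC
1     SiE1 0.444 1.000 0.0    NA 0.400
2     SiE2 0.778 1.000 0.6 0.632 0.750
3     ReIn 0.611 1.000 0.3    NA 0.575
4     DiMe 0.722 0.625 0.8 0.433 0.775

Robustness:
  strategy median_overlap total_markers
1     SiE1          0.222           265
2     SiE2          0.135           253
3     ReIn          0.174           259
4     DiMe          0.291           176

Enrichment factor:
  strategy n_detected_annotated n_true_detected n_identified_annotated
1     SiE1                37066              12                   1902
2     SiE2                36128              12                   1773
3     ReIn                24027              12                    255
4     DiMe                24444              12                   1399
  n_true_identified   ef
1                 9 14.6
2                 7 11.9
3                 5 39.3
4                11 16.0

DiMe-vs-other one-sided rank-sum p-values on overlaps:
    SiE1     SiE2     ReIn 
3.68e-06 1.67e-15 2.46e-12
```

Reading it: merging (DiMe) buys markedly more robust marker lists (median
overlap 0.29 vs 0.14–0.22, rank-sum p ≪ 0.05) and solid classification from
the doubled cohort, while results integration (ReIn) — which intersects the
two experiments' identified metabolites — is the most conservative against
false discoveries (EF 39 from only 255 identified metabolites). The `NA`
MCC entries are flagged zero-denominator cases (the SVM predicted a single
class on a 9-sample independent split), reported as undefined rather
than 0. `write_comparison(cmp, "report/")` writes JSON + CSV tables and an
overlap boxplot.

A command-line interface covering the same pipeline (simulate, pretreat,
merge, markers, classify, robustness, ef, run) is installed at
`<library>/metastrat/exec/metastrat`.

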