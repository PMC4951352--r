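# reosig

Rank-based gene-pair prognostic signatures from within-sample relative
expression orderings (REOs), for transcriptomic relapse-risk analysis
of early-stage cancer cohorts.

## The problem

Risk scores summarized from absolute expression levels depend on
normalization, and therefore on which other samples happen to be
analyzed together: the same patient can change risk group when the
surrounding cohort changes. A relative expression ordering — whether
gene *a*'s value lies above or below gene *b*'s *within one sample* —
is invariant to any strictly increasing per-sample transform, hence
robust to batch effects and normalization, and applicable to a single
patient in isolation.

`reosig` implements the full development cycle of a gene pair
signature (GPS) for relapse-free survival (RFS) of stage II colorectal
cancer, usable for any comparable two-condition, censored-outcome
design:

* **Screening** — per-gene Student's *t* differential expression
  (metastatic stage III/IV vs non-metastatic stage I, BH-FDR < 0.1),
  then a two-sided Fisher exact reversal screen over all gene pairs
  anchored on a DE gene: does the frequency of *E*a > *E*b differ
  between the groups? (BH-FDR < 0.2).
* **Cross-dataset consistency** — overlap of pair lists from two
  datasets, keeping pairs with agreeing reversal direction, scored
  *s/k* with an upper-tail binomial p-value.
* **Prognostic filtering and selection** — univariate Cox models on
  the REO partition of a chemotherapy-naive stage II cohort
  (*p* < 0.01), then greedy forward selection minimizing the log-rank
  p of the majority-vote classification.
* **Classification** — a sample is high-risk when a strict majority of
  signature pairs (2 of 3) show their high-risk orderings inside that
  sample. The published three-pair signature (ORC1–OLR1, MTNR1A–VGLL1,
  RFX5–MMP14, *E*a < *E*b = high risk) ships as `gps3_signature()`.
* **Evaluation** — Kaplan–Meier curves, log-rank tests, (multivariate)
  Cox models, Harrell's C-index, binomial concordance of DE
  directions, hypergeometric overlap and GMT-based category
  enrichment; plus a percentile-threshold voting baseline that
  demonstrates the cohort-dependence the REO approach avoids.
* **Synthetic cohorts** — a ground-truthed generator
  (`synthetic_config()`, `generate_cohort()`) with planted reversed
  pairs, latent relapse risk, censored exponential survival and
  chemotherapy arms, so the whole pipeline is verifiable offline.

## Worked example

Generate a synthetic cohort, classify its chemotherapy-naive stage II
patients with a three-pair signature built from the planted truth, and
evaluate the risk groups:

```r
library(reosig)

cfg    <- synthetic_config(seed = 7)
cohort <- generate_cohort(cfg)

sig <- reo_signature(cohort$truth$planted_pairs[1:3, ])
sig
#> Gene-pair signature: 3 pair(s), high risk at >= 2 vote(s)
#>            rule
#> 1 G0503 < G0627
#> 2 G0252 < G0406
#> 3 G0698 < G0931

ids   <- select_cohort(cohort$clinical, "II", ctx = FALSE)
calls <- classify_gps(cohort$expr, sig, ids)
table(calls$label)
#> high  low
#>   58  142

clin <- cohort$clinical[match(ids, cohort$clinical$sample_id), ]
res  <- compare_survival(clin$rfs_time, clin$rfs_event, calls$label)
sprintf("log-rank p = %.3g, HR = %.2f [%.2f, %.2f], C-index = %.3f",
        res$logrank_p, res$hr, res$ci95[1], res$ci95[2], res$c_index)
#> "log-rank p = 5.23e-10, HR = 3.92 [2.47, 6.22], C-index = 0.679"
```

58 of 200 patients are called high-risk; their relapse hazard is ~3.9
times the low-risk group's (the generator's true latent hazard ratio
is 4), and the binary call orders 68% of usable patient pairs
correctly. Agreement with the latent risk label is 0.97.

The closed-form concordance statistic, here for 41 overlapping DE
genes that all agree in direction:

```r
concordance_score(k = 41, s = 41)
#> score = 1, p = 4.55e-13   (= 0.5^41)
```

The full discovery chain — screening two datasets, consistency
filtering, Cox filtering, forward selection, evaluation, concordance
and chemotherapy-stratified comparisons — is orchestrated by
`run_pipeline(pipeline_config(synthetic = synthetic_config()), "runs/demo")`,
which writes the signature, risk calls, evaluation report and a
machine-readable run log.

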