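# methpattern

Dissects DNA methylation **regulation** in bulk tumor transcriptomes. The
expression of the 24 genes that write (DNMT1, DNMT3A, DNMT3B), erase
(TET1, TET2, TET3) and read (MBD/ZBTB/UHRF families and associates)
5-methylcytosine is used to discover *modification patterns* — sample
subtypes with distinct prognosis and immune microenvironments — and to
build a portable per-patient risk score from them.

For whom: computational biologists analyzing merged expression cohorts
(microarray series, log2 FPKM) with survival annotation, who want the
whole pattern → signature → score → stratification chain as tested R
functions rather than a one-off script.

## The method

1. **Meta-cohort**: cohorts merged on shared genes
   (`merge_cohorts`), batch effects removed by parametric empirical-Bayes
   location/scale adjustment (`combat_adjust`, via sva's ComBat).
2. **Patterns**: consensus NMF (KL multiplicative updates, Monti-style
   80% subsampled restarts) of the 24-regulator sub-matrix
   (`consensus_cluster`), rank by cophenetic correlation (`select_rank`),
   labels from the consensus dendrogram (`assign_patterns`).
3. **Signature**: moderated F-test across patterns with empirical-Bayes
   variance shrinkage (`moderated_f_test`, BH-adjusted p < 0.01), then a
   per-gene univariate Cox screen (`univariate_cox_screen`, Wald
   p < 0.01); the intersection is the prognostic signature
   (`derive_signature`). A second consensus NMF on the signature genes
   gives the corroborating *gene clusters*.
4. **DMS (DNA methylation score)**: PCA on the signature genes; per
   sample,

   `DMS = PC1 projection + PC2 projection`,

   each component sign-oriented so a positive univariate Cox log-HR makes
   *high DMS = worse prognosis* (`fit_dms`, `score_dms`). Patients split
   at the maximally selected rank-statistics cutpoint
   (`optimal_cutpoint`).
5. **Characterization**: ssGSEA single-sample enrichment
   (`ssgsea_scores`), stromal/immune/ESTIMATE-style scores
   (`estimate_scores`), preranked GSEA (`preranked_gsea`), KM / log-rank /
   Cox / time-dependent AUC (`km_estimate`, `logrank_test`, `cox_fit`,
   `time_dependent_auc`), rank and contingency tests, Spearman
   correlation, mutation frequency / TMB / co-occurrence
   (`mutation_summaries`), and CNV gain/loss frequencies
   (`cnv_frequencies`).

A synthetic-cohort generator (`synthetic_config`, `generate_cohort`,
`generate_batched_cohorts`, `generate_immunotherapy_labels`) plants
pattern, survival, batch, immune and mutation structure with full ground
truth; the whole pipeline runs on it end to end (`run_pipeline`).
See `vignettes/methpattern-methods.Rmd` for the models, defaults and
design decisions.

## Worked example

```r
library(methpattern)

cfg <- pipeline_config(
  synthetic = synthetic_config(n_samples = 300, n_genes = 1000, seed = 42),
  k_range = 2:4, n_runs = 10, k_fixed = 3, seed = 42)
b <- run_pipeline(cfg)

table(b$patterns$pattern)
#>   A   B   C
#> 122  93  85
adjusted_rand_index(b$pattern_labels, b$truth$pattern[colnames(b$expression)])
#> 0.98
sum(b$deg$adj_p < 0.01 & !b$deg$flagged)   # DEGs across patterns
#> 459
length(b$signature$genes)                  # prognostic signature
#> 329
b$cutpoint$cutpoint                        # DMS survival cutpoint
#> -3.23
table(b$cutpoint$groups)
#>  low high
#>   86  214
b$survival$logrank_dms                     # high vs low DMS
#> chisq = 99.5, p = 1.9e-23
b$survival$cox_dms$HR[1]                   # hazard ratio per SD of DMS
#> 2.23
b$survival$auc[["t36"]]                    # AUC for 36-month survival
#> 0.867
```

Reading the numbers: the three recovered patterns match the planted
subtypes almost perfectly (ARI 0.98); 459 genes separate them, 329 of
those also carry prognostic signal and form the signature; the DMS split
at −3.23 puts the two high-hazard patterns in the high group, whose
survival is drastically worse (HR 2.2 per SD of score, AUC 0.87 at three
years). On generated data these are recoveries of planted structure, not
biological findings.

Real data enter through `read_expression` (TSV/GCT), `read_clinical`,
`read_gene_sets` (GMT) and `read_mutations` (MAF-like TSV); a thin CLI
wrapper for the pipeline lives at `inst/cli/methpattern.R`.

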