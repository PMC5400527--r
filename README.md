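# prognet

Functional prognostic signatures tie a tumor's clinical outcome to genes
that a transcription factor actually controls. The motivating design:
knock a transcription factor (such as the AP-1 family member Fra-1/FOSL1)
down with two independent shRNAs in two breast cancer cell lines, keep the
probes that respond to both hairpins in both lines, screen them for
prognostic value in a patient cohort, and keep the genes over-expressed
specifically in poor-prognosis patients. The surviving gene set is scored
per patient as a *meta-gene* (the mean of the members' log2 expression),
stratifies patients for Kaplan-Meier / log-rank / Cox analysis, and its
association with tumor grade is summarized across cohorts by a
random-effects meta-analysis of standardized mean differences. On the
regulatory side, ChIP-Seq peak sets for several transcription factors are
intersected, assigned to promoters, classified by genomic region, and the
significance of their co-binding is established by permutation, with
gene-set enrichment analysis connecting binding to knockdown response.

`prognet` implements that entire computational pipeline as composable,
tidyverse-style R functions, plus a seeded synthetic-data module that
generates every input with planted ground truth — so each stage can be
validated against a recoverable answer.

## What is implemented

- **Derivation funnel** (`derive_signature()` and its stages
  `differential_probes()`, `prognostic_probe_filter()`,
  `intersect_and_direction()`, `poor_prognosis_expression_filter()`):
  dual-shRNA Welch t-tests at p < 1e-6, probe-to-gene collapsing with the
  `_at` > `_x_at` > `_s_at` suffix priority, a per-feature median-split
  log-rank screen at p < 0.1, two-cell-line intersection keeping genes
  down-regulated under both hairpins, and the poor-prognosis median
  filter at a 60-month horizon.
- **Survival statistics** (`metagene_score()`, `stratify()`,
  `km_estimate()`, `logrank_test()`, `cox_hr_binary()`): product-limit
  curves, the one-sided log-rank test with z = (O − E)/√V, and the
  binary-covariate Cox hazard ratio with Breslow ties (via the
  `survival` package).
- **Grade meta-analysis** (`hedges_g_star()`,
  `random_effects_combine()`, `run_grade_meta()`): bias-corrected
  standardized mean difference
  g\* = (1 − 3/(4(n₁+n₂) − 9)) · (x̄₁ − x̄₂)/s\*, with
  se² = (n₁+n₂)/(n₁n₂) + g\*²/(2(n₁+n₂−3.94)), combined by
  DerSimonian–Laird with a normal-theory CI; the n ≥ 10 per-grade-group
  eligibility rule and per-patient deduplication are enforced.
- **Peak genomics** (`promoter_windows()`, `assign_peaks_to_genes()`,
  `classify_peaks()`, `multiway_intersection()`,
  `permutation_overlap_test()`, `tss_coverage_matrix()`,
  `gene_set_overlaps()`): −2 kb/+2.5 kb strand-aware promoter windows,
  a priority-ordered region partition (promoter > exon > intron >
  active enhancer > enhancer > intergenic), k-way peak intersection,
  a within-chromosome uniform (or circular-shift) permutation null with
  add-one empirical p, TSS coverage heat matrices and exclusive Venn
  counts.
- **Differential expression & GSEA** (`variation_filter()`,
  `ttest_bh()`, `row_scale_01()`, `metagene_group_compare()`,
  `pearson_correlation()`; `signal_to_noise()`, `enrichment_score()`,
  `gsea_test()`): the 1.5-fold / 1-absolute variation filter, t-tests
  with Benjamini–Hochberg q-values, and a from-scratch weighted
  running-sum GSEA with phenotype permutation (1000 permutations,
  signal-to-noise ranking with the 0.2 sd floors).
- **Synthetic data** (`sim_config()` and five `gen_*()` generators):
  knockdown matrices, a survival cohort whose hazard depends on a
  planted meta-gene, grade-labelled datasets with planted SMD and
  heterogeneity, a toy genome with planted four-factor co-binding, and
  FPKM knockdown tables — all deterministic from one root seed.

Results come back as tibbles or light S3 objects with `tidy()`,
`glance()` and `autoplot()` methods.

## Worked example

```r
library(prognet)

cfg <- sim_config(seed = 7)                       # default study conditions
kd  <- gen_knockdown_experiment(cfg)              # two cell lines, 2 hairpins
co  <- gen_patient_cohort(cfg, kd$truth$gene_id)  # 509 patients, HR = 3

sig <- derive_signature(kd$cell_lines$A, kd$cell_lines$B,
                        kd$probe_map, co$expr, co$clinical)
funnel_report(sig)
#>   stage              n
#> 1 differential_A    30
#> ...
#> 8 poor_prognosis    30

st <- stratify(metagene_score(co$expr, sig$gene_id))
logrank_test(co$clinical[st$group == "high", ],
             co$clinical[st$group == "low", ])
#> Log-rank test (n = 509)
#>   chi-square = 119.7988, z = 10.9453
#>   two-sided p = 7.001e-28, one-sided p (A worse) = 3.501e-28
cox_hr_binary(co$clinical, st$group)
#> Cox proportional hazards (binary covariate, Breslow ties)
#>   HR = 3.439 [2.726, 4.339], p = 1.967e-25, n = 509

run_grade_meta(gen_grade_datasets(cfg))
#> Random-effects meta-analysis (DerSimonian-Laird), k = 10
#>   combined SMD = 0.8179 (se 0.1178), 95% CI [0.5870, 1.0488]
#>   tau^2 = 0.0467, Q = 13.671, p = 3.85e-12

gp <- gen_genome_peaks(cfg)
permutation_overlap_test(gp$peaksets, gp$chrom_sizes,
                         n_perm = 999, seed = 7)
#> Permutation overlap test (uniform null, 999 permutations)
#>   observed k-way regions = 60, null mean = 0.06, p = 0.001
```

The funnel recovers all 30 planted signature genes with no false
positives; the stratified cohort shows the planted hazard ratio of 3
(within its confidence interval); the meta-analysis recovers the planted
standardized mean difference of 0.8; and the 60 four-factor peak regions
(matching the 60 planted co-bound promoters) are far beyond the permutation null,
whose add-one p bottoms out at 1/1000.

## Vignette

`vignettes/prognet-methods.Rmd` describes the statistical model behind
each stage, the tunable parameters and their defaults, what the
synthetic generators do and do not emulate, and the package's known
limitations.
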