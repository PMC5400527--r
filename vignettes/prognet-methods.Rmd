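---
title: "Methods: signature derivation, survival meta-analysis, and co-binding analytics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: signature derivation, survival meta-analysis, and co-binding analytics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prognet)
```

`prognet` implements a pipeline that connects a transcription factor's
functional targets to patient prognosis and to coordinated genome
binding. This vignette is the package's account of the statistics it
computes: the model behind each stage, the parameters that matter, the
numerical conventions, and what the synthetic-data validation does and
does not establish.

## The derivation funnel

The signature is built in four filtering stages, each of which can only
shrink the candidate set:

1. **Dual-hairpin differential screen.** For each of two cell lines, a
   probe qualifies if a Welch two-sample t-test of control vs knockdown
   is below `alpha` (default `1e-6`) for *both* independent shRNA
   hairpins, with agreeing signs of the mean difference. Requiring two
   hairpins at a severe threshold is what controls off-target effects;
   the severe `alpha` makes the false-positive contribution of the
   ~10^3-probe array negligible. The test defaults to Welch because
   per-probe variances on arrays are not homogeneous; a pooled-variance
   flag exists.
2. **Probe-to-gene mapping.** `collapse_probes()` keeps, per gene, only
   probes of the best available suffix class in the order
   `_at` > `_x_at` > `_s_at` and averages the remainder element-wise.
   This priority is the literal order stated in the source protocol even
   though the common array convention ranks `_s_at` above `_x_at`; the
   order is therefore an explicit argument (`priority =`) rather than a
   constant.
3. **Prognostic screen.** Each mapped gene is tested on a training
   cohort: patients are split at the gene's median expression (strictly
   greater than the median goes to the high group, so ties go low — a
   deterministic rule that needs no randomization) and a two-sided
   log-rank test at `p < 0.1` decides retention. The grouping rule for
   this screen is not uniquely dictated by the design, so the split
   quantile is an argument (`q =`). Degenerate splits (fewer than two
   patients on a side, e.g. constant genes) are skipped with a warning
   rather than producing meaningless statistics.
4. **Intersection, direction, and poor-prognosis filters.** Genes must
   appear in both cell lines' prognostic sets with direction
   down-in-knockdown in both; then patients are labelled *poor* (event
   before `horizon_months`) or *good* (event-free with follow-up at
   least `horizon_months`; everyone else is excluded) and a gene
   survives only if its median expression in the poor group exceeds its
   overall cohort median while its median in the good group falls below
   it. The horizon defaults to 60 months — the conventional five-year
   prognosis boundary in breast cancer — and is a flag because the
   poor/good definition is a design choice, not a derived quantity.

The funnel report records the count surviving each stage; monotonicity
of those counts is a tested invariant.

## Survival statistics

The meta-gene of a gene set is the unweighted per-sample mean of the
members' log2 expression; averaging over correlated members suppresses
single-gene noise, which is the entire point of scoring patients by a
set rather than a gene. Stratification uses a median split by default
(ties low); the published analyses this mirrors defer their cutoff to an
earlier protocol, so the rule is exposed (`rule = "fraction", q =`)
rather than hard-coded.

Kaplan-Meier curves, the log-rank test and the Cox model are computed
through the `survival` package. The log-rank z statistic is
\((O_A - E_A)/\sqrt{V}\) with the hypergeometric variance summed over
distinct event times; the one-sided p-value \(\Phi(-z)\) tests the
directional hypothesis that the signature-high group does worse, which
is the convention used throughout (a flag flips it by swapping the
groups). The Cox hazard ratio uses Breslow tie handling — adequate here
because a single binary covariate with continuous simulated times
rarely ties — with a Wald 95% CI. Monotone partial likelihoods
(complete separation of event times) are flagged in the result instead
of silently returning a diverged estimate.

## Grade meta-analysis

Per dataset, the grade III vs grade I effect is the bias-corrected
standardized mean difference

$$ g^* = \left(1 - \frac{3}{4(n_1+n_2)-9}\right)
   \frac{\bar x_1 - \bar x_2}{s^*}, \qquad
   s^* = \sqrt{\frac{(n_1-1)s_1^2 + (n_2-1)s_2^2}{n_1+n_2-2}} $$

with standard error
\(\mathrm{se}^2 = \frac{n_1+n_2}{n_1 n_2} + \frac{(g^*)^2}{2(n_1+n_2-3.94)}\).
The plain-text rendering of this SE formula is typographically
ambiguous; the form implemented is the standard Hedges–Olkin
approximation, the only reading consistent with every printed token.
Datasets need at least 10 tumors in each grade group (smaller groups
make \(g^*\) unstable and the eligibility rule is part of the protocol);
duplicate patients are deduplicated keeping the first record.

Effects are combined by DerSimonian–Laird: method-of-moments
\(\hat\tau^2 = \max(0, (Q-(k-1))/(\sum w - \sum w^2/\sum w))\),
random-effects weights \(1/(se_i^2+\hat\tau^2)\), and a normal-theory
95% CI. DL is the default because the protocol names only "a random
effects model" and DL is the field's default; the implementation is
cross-checked against `metafor` in the test suite. **Known limitation:**
the DL normal-theory CI undercovers slightly for small numbers of
studies with heterogeneity. In the package's own simulations (k = 10,
planted SMD 0.8, between-study sd 0.2, per-group n in 10–40), coverage
runs about a point below the nominal 95%, and `metafor` reproduces the
same coverage exactly on identical inputs — a property of the
estimator, not of the implementation. A Knapp–Hartung-type adjustment
would improve coverage further but would depart from the normal-theory
CI the protocol specifies.

## Peak genomics

All interval work uses 0-based half-open coordinates (the BED
convention) internally; 1-based sources are converted on load, so there
is a single off-by-one surface at the I/O boundary. Promoters are
−2 kb/+2.5 kb around the TSS, strand-aware and clipped at chromosome
ends. "Bound" means ≥ 1 bp of overlap — no minimum-fraction rule is
implied by the design, so `min_overlap` is an argument.

Region classification assigns each peak exactly one category by the
priority promoter > exon > intron > active enhancer > enhancer >
intergenic, making the counts a partition (a tested invariant).
"Enhancer" means overlap with the H3K4me1-like mark outside promoters
and gene bodies; "active enhancer" additionally requires the
H3K27ac-like mark. The source phrasing ("both ... and/or") is
self-contradictory, so the alternative reading — activity mark alone
suffices — is selectable via `active_rule`.

The k-way intersection is the set of maximal regions covered by at
least one peak from *every* input set, merged; its cardinality is the
"number of intersecting peaks". (Counting units are a genuine choice —
summits, whole peaks, slopped peaks; whole-peak regions are the
default and only implemented unit.) The permutation test holds set 1
fixed and repositions every peak of the other sets uniformly within its
own chromosome, preserving lengths and allowing collisions; the
empirical p uses the add-one estimator \((1 + \#\{null \ge obs\})/(1+n)\)
so p is never 0. A circular-shift null (one rotation per chromosome per
set, wrap-around peaks split) is available for users who want to
preserve intra-set spacing. Under an independence null the add-one p is
approximately uniform; the test suite checks this with a
Kolmogorov–Smirnov test across 200 simulated genomes.

TSS coverage matrices sum per-bin coverage with multiplicity across a
±10 kb window (bin width 500 bp by default), reverse minus-strand rows
so bins run 5′→3′, and order rows by the ranking factor's best in-window
peak score.

## Differential expression and GSEA

The FPKM variation filter keeps genes with
\((\max+\epsilon)/(\min+\epsilon) \ge 1.5\) and \(\max-\min \ge 1\),
with \(\epsilon = 0.001\) guarding against zero FPKMs (zeros are real
in RNA-Seq; the pseudo-count is the smallest value that cannot change a
call on biologically expressed genes). The DE test is a plain
pooled-variance t-test — matching an unqualified "t-test" — with Welch
behind a flag, followed by Benjamini–Hochberg step-up q-values
(`stats::p.adjust`), which the suite verifies against a brute-force
min-over-tail oracle bitwise. Heat-map display scaling maps each row
affinely to [0, 1]; constant rows map to 0.5 (the only neutral choice)
with a warning.

GSEA is implemented from scratch. Signal-to-noise scores
\((\mu_A-\mu_B)/(\sigma_A+\sigma_B)\) floor each group sd at
\(\max(0.2|\mu|, 0.2)\) — the published desktop-GSEA convention,
configurable — and ties in the ranking break by gene id so the
permutation null is deterministic given the seed. The running sum
increments by the hit's \(|score|^p\) share (p = 1) and decrements by
\(1/(N-|S|)\) per miss; ES is the signed maximum deviation. The null
comes from phenotype permutations (default 1000); NES divides ES by the
mean |null ES| of the same sign, and for a single gene set the reported
FDR reduces to the nominal add-one p.

## The synthetic-data module

Every generator is driven by one `sim_config()` and a single root seed
from which per-generator child seeds are derived (so any one input can
be regenerated alone; R's Mersenne-Twister is the documented RNG). The
defaults are the study conditions the package is validated under:

| parameter | default | what it encodes |
|---|---|---|
| `kd_effect_log2`, `noise_sd`, `n_reps` | 2, 0.1, 6 | a strong, clean knockdown: per-arm power sufficient for p < 1e-6 |
| `n_patients`, `hazard_ratio`, `censor_rate` | 509, 3, 0.3 | the training-cohort scale and a clinically large planted effect |
| `n_grade_datasets`, `planted_smd`, `tau` | 10, 0.8, 0.2 | ten eligible cohorts, a large grade effect, moderate heterogeneity |
| `n_chroms`, `chrom_len`, `n_genes` | 3, 1 Mb, 200 | a desk-scale genome where permutation nulls are cheap |
| `peaks_per_factor`, `cobind_fraction`, `peak_len` | 300, 0.3, 400 | realistic peak density with a planted co-binding excess |

The survival model is exponential with a binary group hazard (log-hazard
`log(hazard_ratio)` for patients whose true meta-gene exceeds its
median), which gives closed-form expectations for checking log-rank and
Cox recovery. Censoring is independent Uniform(0, c) with c solved
numerically to hit the target censored fraction. Signature genes load
0.7 on one shared latent factor per patient, so the meta-gene tracks
risk more tightly than any single member — the property that justifies
meta-gene scoring. Co-bound promoters receive one peak per factor
jittered (±100 bp) around a shared anchor, so planted co-binding is
visible both at promoter level and as base-level k-way overlap.

What the generators deliberately do **not** emulate: probe-level array
intensity models (inputs are already-summarized log2 matrices; RMA
background correction is out of scope), read-level RNA-Seq noise
(FPKM tables are log-normal), correlated background genes, batch
effects, non-proportional hazards, and peak-width/GC biases of real
ChIP-Seq. Passing tests therefore demonstrate algorithmic correctness
and statistical calibration under clean models — not robustness to
those real-data pathologies.

## Numerical conventions and degenerate inputs

- Quantile normalization resolves within-column ties by the mean of the
  reference values at the tied ranks (`limma::normalizeQuantiles`,
  `ties = TRUE`); median centering is exactly idempotent.
- All median/quantile splits send ties to the low group.
- Missing expression values are rejected by default; an explicit
  `allow_na` mode mean-imputes per feature and reports the count.
- Zero-variance probes with zero mean difference are excluded from the
  differential screen (their t statistic is undefined).
- Empty peak files load as empty sets with a warning; peaks longer than
  their chromosome, intervals with `end <= start`, negative survival
  times, unknown grade/endpoint labels, and TSSs outside their
  chromosome are hard errors at the I/O boundary.
- Cox fitting stops after 50 Newton-Raphson iterations and flags
  monotone likelihoods; add-one permutation p-values are never 0.

## Problem sizes used in validation

The test suite validates calibration at desk scale: 500 meta-analysis
replicates, 1000 null cohorts of 200 patients, 200 Cox recovery runs at
n = 2000, 50 full funnel replicates, 100 random genomes against the
per-base-pair intersection oracle, 200 permutation-null uniformity
runs, and 1000-fold brute-force oracles for BH and the GSEA running
sum. These sizes give binomial standard errors comfortably inside the
asserted bands while keeping the whole suite fast to run.

## Known limitations

- The package consumes summarized expression matrices and called peaks;
  it does not reimplement array background correction, read alignment,
  FPKM estimation, or peak calling.
- Only a single binary covariate is supported in the Cox model — the
  stratified meta-gene design needs nothing more; multivariate or
  time-varying models are out of scope.
- The DL random-effects CI undercovers at small k (see above).
- Multi-set GSEA FDR (positive/negative null pooling across sets) is
  not implemented; the single-set FDR equals the nominal p.
- Live probe-annotation lookups are out of scope; probe maps are
  supplied as tables.
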