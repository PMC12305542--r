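---
title: "Quantifying subgenome expression bias in homoeolog pairs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying subgenome expression bias in homoeolog pairs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(homeobias)
```

## The problem

An allopolyploid such as oilseed rape carries two complete parental genomes
(here labelled A and C). For most genes the nucleus therefore holds a
*homoeolog pair*: one A-subgenome copy and one C-subgenome copy of the same
ancestral gene. Whether the two copies are transcribed equally — and whether
any asymmetry is tissue- or stage-specific — is a central question in
polyploid biology. This package quantifies that asymmetry at three levels:

1. **Whole-transcriptome summaries** per sample: how many genes from each
   subgenome are detected (TPM strictly above a threshold, default 1), what
   fraction of total TPM each subgenome contributes, and how the most highly
   expressed genes (top 500/1,000/1,500/5,000) split between subgenomes.
2. **Per-pair bias**: for each homoeolog pair and condition, the statistic
   $$v = \log_2\frac{\mathrm{TPM}_A + \varepsilon}{\mathrm{TPM}_C + \varepsilon},$$
   classified with inclusive thresholds into `A_BIAS` ($v \ge 2$), `C_BIAS`
   ($v \le -2$), `LOW_BIAS` ($|v| \le 0.1$) or `INTERMEDIATE` (everything
   between the bands). The strong cutoff of 2 corresponds to a four-fold
   expression difference.
3. **Bias-profile structure**: hierarchical clustering of the pair-by-condition
   bias matrix, with recursive k-cuts of selected clusters, followed by
   pair-level term enrichment of the resulting gene-pair lists.

## Conventions and numerical choices

**Pseudocount.** One homoeolog of a detectable pair may have zero TPM, which
makes the raw ratio undefined. We add $\varepsilon$ (default 0.01 TPM) to
both numerator and denominator. The value is configurable and recorded in the
run manifest; note that at the classification boundary the pseudocount
matters — TPM 40 vs 10 gives $\log_2(40.01/10.01) \approx 1.9989$, which is
`INTERMEDIATE`, not `A_BIAS`.

**Universe rule.** A pair enters a condition's universe iff at least one
member exceeds the detection threshold (`max(TPM_A, TPM_C) > 1`), i.e. the
detection rule applied to "either gene". Cells outside the universe are
`UNDETECTED`; their values are `NA` and excluded from tallies and from the
clustering input. The four class counts always partition the universe, so
conservation is checkable on any input.

**Replicate handling.** Replicates are averaged on the TPM scale
(gene-wise arithmetic mean) *before* the ratio is taken, matching a data
model with one expression value per condition. Ratio-then-average is the
natural alternative; averaging first is less volatile when one replicate has
a near-zero denominator.

**Intermediate class.** Values in $(-2, -0.1) \cup (0.1, 2)$ belong to no
named band but must be countable for the partition property, so they form an
explicit fourth class.

**Ranking ties.** Top-N composition breaks TPM ties by lexicographic gene
id. This matters only for exactly tied values but makes results
deterministic across platforms.

**Clustering.** Euclidean distance, complete linkage by default (average and
Ward available). Pairs with any `UNDETECTED` cell across the clustered
columns are excluded (complete-case), because Euclidean distance is
undefined on missing values; `subset_bias()` lets you cluster on a condition
subset so that sparsely expressed conditions do not decimate the row set.
Agglomeration, cutting and the resulting nesting guarantee are delegated to
`stats::hclust`/`stats::cutree`, which are deterministic for a fixed input
ordering; since bias values are continuous, exactly tied merge heights have
probability zero and no bespoke tie rule is imposed. Cluster labels are
re-assigned by decreasing size (1-based) for stable reporting, and clusters
with fewer than 60 members (strict) are flagged out of reports without
deleting membership.

**Enrichment.** The test is the one-sided hypergeometric upper tail
(Fisher's exact upper tail) on pair counts: population $N$ = the clustered
pair universe (not the whole genome — clusters must be judged against what
was clusterable), $K$ = annotated pairs in it, $n$ = cluster size, $k$ =
annotated pairs in the cluster. A pair inherits the union of its members'
terms by default (`either_homoeolog`; homoeologs overwhelmingly share
function), with intersection available for stringency. Default significance
is raw $p < 0.001$ with a support filter of at least two annotated pairs;
Benjamini–Hochberg adjustment is optional and, when selected, significance
is judged on adjusted values.

**Relative-expression export.** The eFP-style per-gene profile is
$\log_2((\mathrm{TPM}_c + \varepsilon)/(\mathrm{median} + \varepsilon))$
with the median over *all* conditions of the supplied matrix; restricting
the median (e.g. within a stage) is done by subsetting the matrix first.
Undetected conditions are included in the median.

## The synthetic-data generator

`simulate_homoeologs()` emulates the study design the package targets: a
laser-microdissection-style atlas of seed subregions across development.
Defaults (chosen once as the simulated study conditions):

| parameter | default | rationale |
|---|---|---|
| pairs / singletons | 2,000 / 500+500 | 5,000 genes keeps every top-N summary computable at desk scale |
| conditions | 26 | ISC/OSC/CZSC/CPT at OV/GLOB/HEART/MG; MCE/PEN/CZE/EP at GLOB/HEART; COT/ROOT at MG |
| replicates | 3 | typical of pooled-section designs |
| global C share | 0.55 | a clear but realistic global asymmetry |
| class probabilities | A 0.05, C 0.065, low 0.08 | ~11.5% strongly biased with a C lean, a realistic magnitude for a strongly biased tissue |
| strong effect | 3 ± 0.3 log2 | strong pairs sit well inside the $|v| \ge 2$ band |
| NB dispersion | 0.02 | moderate replicate reproducibility |
| library size | 5e6 | deep enough that count noise is secondary to dispersion |

Pairs draw a log-normal baseline; the A/C split of each pair's total follows
its class's log-ratio (intermediates uniform in $\pm(0.1, 2)$). Condition
effects multiply the pair total, so they cancel in the ratio. The global C
share is calibrated by scaling *unpaired* C genes against the realized
baselines — this hits the target share exactly in expectation without
distorting any pair's ratio. Mature-embryo conditions (MG stage of EP, COT,
ROOT) express only a configurable fraction of genes (default 0.3), with 20
designated storage pairs rescaled to absorb 60% of the transcript pool,
emulating a storage-dominated mature embryo.

What the generator does **not** emulate: mapping bias between subgenomes,
homoeolog cross-mapping, batch effects, compositional coupling between
conditions, or realistic GO-term topology (planted terms are flat sets).
Passing recovery tests therefore demonstrates correctness of the
computations under a declared model, not performance on real libraries.

**Recovery conventions.** Per-condition class calls are noisy at the narrow
low-bias band ($\pm 0.1$ spans a fraction of the replicate-level ratio
noise), so `recovery_report()` assesses strong-class *recall* per cell but
estimates the planted strong-bias *fraction* at the pair level, classifying
each pair's across-condition **median** log-ratio: the planted class is a
per-pair property, and the median is robust to condition-specific extremes
such as the mature-embryo masking. Cluster-recovery checks subset to the 16
seed-coat conditions, where complete-case rows are the norm.

## Problem sizes used by the test-suite and acceptance runs

Unit tests run on a reduced design (200 pairs, 4 conditions, 2 replicates).
Property and recovery checks use the full default configuration (2,000
pairs, 26 conditions, 3 replicates), 100 random small instances for the
brute-force agglomeration oracle, the complete $N \le 12$ grid for the
hypergeometric enumeration oracle, and 10,000 null draws for the p-value
uniformity check. These sizes make every check reproducible on a single CPU
in minutes.

## A worked example

```{r example}
sim <- simulate_homoeologs(simulation_config(seed = 1))
tpm <- tpm_normalize(sim$counts, sim$lengths)
cond <- aggregate_replicates(tpm, sim$metadata)
bias <- pair_bias(cond, sim$pairs)
bias_tally(bias)[1:4, ]
```

```{r recovery}
rec <- recovery_report(sim$truth, bias = bias)
c(strong_recall = rec$strong_recall,
  strong_fraction_est = rec$strong_fraction_est,
  strong_fraction_planted = rec$strong_fraction_planted)
```

## Known limitations

- The bias statistic is descriptive: fixed thresholds, no per-pair
  significance test (no binomial or likelihood ratio test) and no shrinkage;
  pairs near the detection threshold have noisy ratios that only the
  pseudocount tempers.
- Only TPM normalization is provided. Between-sample methods (TMM, quantile)
  are out of scope, so comparisons across very different library
  compositions inherit TPM's compositional caveats.
- Enrichment takes annotations as given: no GO-graph propagation and no
  ortholog mapping.
- Clustering requires complete cases; mean-imputation is deliberately not
  silently applied. Choose the clustered conditions so that missingness is
  rare.
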