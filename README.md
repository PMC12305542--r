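# homeobias

Subgenome expression bias analysis for allopolyploid homoeolog pairs.

## What problem this solves

Allopolyploids (e.g. oilseed rape, *Brassica napus*, AACC) carry two
complete parental genomes, so most genes exist as a homoeolog pair: one
A-subgenome and one C-subgenome copy. Researchers profiling such species
with RNA-seq — particularly across dissected tissues and developmental
stages — need to ask whether transcription favours one subgenome, where,
and for which gene sets. `homeobias` takes a gene × sample count (or TPM)
matrix, a gene → subgenome map and a homoeolog-pair table, and computes:

- **TPM normalization** and whole-transcriptome subgenome summaries per
  sample and per replicate-averaged condition: detected genes (TPM > 1),
  summed-TPM shares, and the subgenome composition of the top
  500/1,000/1,500/5,000 expressed genes;
- the per-pair bias statistic
  **log₂((TPM_A + ε)/(TPM_C + ε))** with inclusive threshold
  classification: `A_BIAS` (≥ 2), `C_BIAS` (≤ −2), `LOW_BIAS` (|v| ≤ 0.1),
  `INTERMEDIATE` otherwise, and `UNDETECTED` when neither member exceeds
  1 TPM; per-condition tallies partition the detectable universe;
- **hierarchical clustering** (Euclidean, complete linkage) of the
  pair × condition bias matrix with recursive k-cuts, size-ordered labels
  and a <60-member reporting filter, plus condition dendrograms exported
  as Newick;
- **pair-aware term enrichment**: one-sided hypergeometric tests on pair
  counts against the clustered universe, with a ≥2-pair support filter and
  optional Benjamini–Hochberg adjustment;
- **eFP-style relative-expression exports**:
  log₂(TPM / median TPM across conditions) per gene, in a long-format
  table ready for expression-browser loading;
- a **negative-binomial simulator** with recorded ground truth (per-pair
  classes and log-ratios, expected subgenome shares, planted clusters and
  annotation terms) that emulates a multi-subregion × multi-stage seed
  dissection design, including a storage-gene-dominated mature embryo.

See `vignettes/homoeolog-bias.Rmd` for the model, conventions and design
decisions.

## Worked example

```r
library(homeobias)

sim  <- simulate_homoeologs(simulation_config(seed = 1))
tpm  <- tpm_normalize(sim$counts, sim$lengths)   # columns sum to 1e6
cond <- aggregate_replicates(tpm, sim$metadata)  # replicate means
bias <- pair_bias(cond, sim$pairs)
bias_tally(bias)[1:4, ]
#>   condition n_A_bias n_C_bias n_low_bias n_intermediate n_universe pct_strong pct_low
#> 1     ovCPT      148      167        114           1570       1999       15.8     5.7
#> 2    ovCZSC      143      161        110           1586       2000       15.2     5.5
#> 3     ovISC      137      158        119           1586       2000       14.8     6.0
#> 4     ovOSC      147      158        117           1577       1999       15.3     5.9
```

Each row tallies, for one condition (stage prefix + subregion, e.g.
`ovCPT` = chalazal proliferating tissue of the ovule), how many homoeolog
pairs are strongly A-biased, strongly C-biased, essentially unbiased, or
in between, out of the `n_universe` pairs with detectable expression of
either member. Recovery against the simulator's recorded truth:

```r
rec <- recovery_report(sim$truth, bias = bias)
c(strong_recall = rec$strong_recall,
  strong_fraction_est = rec$strong_fraction_est,
  strong_fraction_planted = rec$strong_fraction_planted)
#>           strong_recall     strong_fraction_est strong_fraction_planted
#>                  0.9824                  0.1240                  0.1150
```

98% of strongly biased pair-condition cells are called with the correct
direction, and the pair-level strong-bias fraction (12.4%) recovers the
planted 11.5% within binomial sampling error. The mean C-subgenome TPM
share across regular samples is 0.5501 against the configured 0.55.

An end-to-end run on an on-disk bundle:

```r
write_bundle(sim, "bundle/")
res <- run_pipeline("bundle/", "out/",
                    clustering = clustering_config(k_top = 9,
                                                   k_sub = list("1" = 5)))
```

which writes `subgenome_summary.tsv`, `bias_matrix.tsv`,
`bias_classes.tsv`, `bias_tally.tsv`, `clusters.tsv`, `cluster_sizes.tsv`,
`condition_dendrogram.nwk`, `enrichment.tsv`, `efp_long.tsv` and a JSON
run manifest with input checksums.

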