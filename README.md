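# degoverlap

Overlap and concordance analysis of TF-dependent transcriptomes.

When several transcription factors (TFs) with unrelated DNA-binding
specificities each rescue the same mutant phenotype, the sets of genes whose
mRNA accumulation depends on each TF can be (i) independent and
non-overlapping, (ii) independent but overlapping by chance, or (iii)
*constrained* — drawn from a common regulated core far more often than
independence allows. `degoverlap` is a post-processing toolkit that takes
per-contrast differential-expression (DE) result tables (DESeq2 dialect:
gene id, baseMean, log2FoldChange, pvalue, padj) and decides between these
outcomes. It is aimed at anyone comparing the DEG sets of two or more DE
contrasts over related tissue.

## What it computes

**Overlap null.** For DEG sets of sizes `D_1..D_k` within expressed-gene
universes of sizes `N_1..N_k` (base mean > 1; padj < 0.05, both strict),
the expected shared count under independence is

```
E = prod_i (D_i / N_i) * mean(N_i)
```

and the Monte Carlo null re-enacts the sampling: per replicate each
analysis draws `D_i` distinct labels uniformly from `{1..N_i}` and the
count common to all k draws is recorded. 1,000 replicates give an
order-statistic 95% CI (the 25th-smallest and 25th-largest simulated
counts) and a z-score `(observed − simulated mean) / simulated sd`. An
observed intersection above the CI rejects independent regulation. With
equal universes and k = 2 the null is exactly
`Hypergeometric(N, D1, D2)`, which the test suite uses as an oracle.

**Concordance.** Paired log2-fold-change (L2FC) scatter classification
(shared strong/weak, single-table strong/weak, weak-in-both, NA-excluded),
Pearson correlations over the union and shared DEG subsets, OLS regression
on the shared subset, outlier-sensitivity refits, k-table sign concordance,
nestedness fractions and discordant-regulation counts.

**Utilities.** Normalization of count matrices to the highest library
total, counts/kb, and transgene/endogenous expression ratios reported at
two significant figures.

**Synthetic data.** A generator for the three regimes (`independent`,
`disjoint`, `constrained`) with a tunable shared core (fraction `rho` of
each TF's DEGs), shared-vs-specific effect-size decomposition
(`sigma_g`, `sigma_e`; the expected shared-subset correlation is
`sigma_g^2 / (sigma_g^2 + sigma_e^2)`), padj values straddling the 0.05
threshold, and NA injection — so the whole pipeline is testable without
external data.

## Worked example

Generate a constrained study (4 TFs, universes of 10,000 genes, 1,000 DEGs
each, a 1,500-gene core supplying 80% of every TF's DEGs), then test all
pairwise overlaps against the resampling null:

```r
library(degoverlap)

cfg <- regime_config("constrained", n_tfs = 4, universe_size = 10000,
                     deg_count = 1000, core_size = 1500, rho = 0.8, seed = 42)
tables <- gen_de_tables(cfg)
sets <- lapply(tables, deg_set)
report <- overlap_report(sets, max_order = 2, n_reps = 1000, seed = 42)
report[, c("comparison", "shared", "expected", "ci_low", "ci_high",
           "simulated_mean", "simulated_sd", "z", "call")]
#>   comparison shared expected ci_low ci_high simulated_mean simulated_sd    z  call
#> 1    TF1,TF2    436      100     83     118          100.2         9.15 36.7 above
#> 2    TF1,TF3    441      100     84     118           99.8         9.06 37.6 above
#> 3    TF1,TF4    460      100     82     118          100.2         9.03 39.8 above
#> 4    TF2,TF3    433      100     82     117          100.2         9.06 36.8 above
#> 5    TF2,TF4    443      100     81     118           99.5         9.29 37.0 above
#> 6    TF3,TF4    437      100     82     118           99.9         9.30 36.3 above
```

Every pair shares ~440 genes where independence predicts 100 (CI 81–118):
all calls are `above`, i.e. the sets behave as a constrained core, not as
independent draws. The paired fold changes agree too:

```r
concordance_summary(tables$TF1, tables$TF2)
#> concordance TF1 vs TF2: r(union) = 0.383, r(shared) = 0.826
#>   shared regression: slope 0.814, intercept 0.037, R^2 0.682 (n = 436)
#>   discordant shared genes: 87
```

The shared-DEG correlation (0.826) approaches the generator's target
`1 / (1 + 0.5^2) = 0.8`, and the near-unit slope says both TFs move shared
genes by similar magnitudes. Transgene abundance ratios work from replicate
counts/kb:

```r
attr(expression_ratio(310, 170), "rounded")
#> [1] 1.8
```

For end-to-end runs, `run_config()` + `run_full_pipeline()` write an
overlap report TSV, per-pair categorized-point TSVs, a Pearson matrix
(union correlations in the lower triangle, shared in the upper) and a
combined JSON report, all bit-reproducible from the seed.

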