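---
title: "Methods: overlap nulls and concordance statistics for TF-dependent transcriptomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: overlap nulls and concordance statistics for TF-dependent transcriptomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(degoverlap)
```

## The scientific question

When several transcription factors (TFs) each rescue the same mutant
phenotype despite recognising different DNA-binding sites — phenotypic
nonspecificity — their downstream transcriptomes can relate to one another in
three qualitatively different ways: the TF-dependent gene sets may be
independent and essentially non-overlapping, independent but overlapping by
chance, or *constrained*, i.e. drawn from a common regulated core far more
often than independence allows.  `degoverlap` implements the downstream
statistics that separate these outcomes from per-contrast differential
expression (DE) result tables: a resampling null for multi-way DEG-set
overlap, and concordance analyses of paired log2 fold changes (L2FC).

The package deliberately starts *after* the DE model.  Alignment, counting
and the negative-binomial DE fit itself are out of scope; the inputs are
DESeq2-dialect result tables (gene id, baseMean, log2FoldChange, pvalue,
padj, with `NA` allowed wherever the DE machinery filtered a gene out).

## Universes, DEG sets and thresholds

Each analysis defines its own **expressed-gene universe**: genes with base
mean strictly greater than `base_mean_min` (default 1).  The low threshold is
intentional — when the question is the *structure* of a TF-dependent
transcriptome rather than the importance of individual genes, every gene the
DE model could have called should stay in the frame, and no effect-size
filter is applied for the same reason.  A **DEG set** is the subset of the
universe with a present adjusted p-value strictly below `alpha` (default
0.05).  Both inequalities are strict; boundary values are excluded, and a
gene whose `padj` is `NA` is never a DEG although it may well be expressed.

## The overlap null

For DEG sets of sizes $D_1,\dots,D_k$ within universes of sizes
$N_1,\dots,N_k$, the analytic expectation under independence is

$$ E = \prod_{i=1}^{k} \frac{D_i}{N_i} \times \overline{N}, $$

the product of the per-analysis DEG fractions scaled by the mean universe
size; for $k = 2$ this is the familiar
$\frac{D_1}{N_1}\frac{D_2}{N_2}\,\overline{N}$.  The Monte Carlo null
re-enacts the sampling directly: in each replicate, analysis $i$ draws $D_i$
distinct integer labels uniformly from $\{1..N_i\}$ and the number of labels
common to all $k$ draws is recorded.  With equal universes and $k = 2$ the
replicate count is exactly $\mathrm{Hypergeometric}(N, D_1, D_2)$, which the
test suite uses as an oracle, alongside exhaustive enumeration of all draw
combinations for tiny instances (`enumerate_overlap_oracle()`).

Two deliberate numerical choices:

* **Mean- vs min-weighted expectation.**  The integer-labelling scheme can
  only share labels up to $\min_i N_i$, so its exact expectation is
  $\prod_i (D_i/N_i)\,\min_i N_i$ — identical to the analytic formula when
  universes are equal, smaller otherwise.  `overlap_report()` computes both
  (`expected` and `expected_exact`) and flags rows where they diverge by
  more than 5%, rather than silently preferring either convention.
* **Per-analysis vs common universe.**  The faithful scheme lets every
  analysis resample within its own universe, implicitly identifying the
  low-indexed genes across analyses.  A second mode
  (`universe_mode = "common"`) resamples every analysis within the
  intersection of the actual universes; the per-analysis scheme is the
  default because it is the convention the reported tables follow.

The **95% CI** is an order-statistic interval: with 1000 replicates, the
25th-smallest and 25th-largest simulated counts (2.5% trimmed from each
end); in general the $\max(1, \mathrm{round}(0.025\,n))$-th order statistic
from each end, requiring at least 40 replicates.  Bounds are inclusive, and
`independence_call()` returns `within` / `above` / `below` accordingly.  The
**z-score** is $(\mathrm{observed} - \hat\mu)/\hat\sigma$ with the sample
standard deviation ($n-1$ denominator; the convention is not dictated by the
method, and at 1000 replicates the difference is negligible).  A degenerate
null ($\hat\sigma = 0$, e.g. when one draw is the whole universe) yields a
flagged `NA`, never an infinity.

Reports enumerate every subset of 2..`max_order` analyses; each subset gets
a sub-seed hashed from the run seed and the sorted labels, so extending a
report never perturbs existing rows.  Observed "shared genes" are plain
k-way intersections, not exclusive Venn regions — a (k+1)-way row can never
exceed its k-way parents — while `venn_region_counts()` provides the
exclusive partition when a Venn-diagram-style breakdown is wanted.

## Concordance of paired fold changes

`pair_tables()` joins two tables on gene id over the union of their
universes; a pair with a missing L2FC on either side is retained only as an
`excluded_na` record and contributes to no statistic, since the DE machinery
filtered that gene in one analysis and the pair is uninterpretable.
`classify_points()` reproduces the standard colour classes of paired-L2FC
scatter plots with the precedence: significant in both → `shared_strong` /
`shared_weak`; significant in exactly one → `either_weak_both` when both
axes sit inside the weak band, otherwise `x_only_*` / `y_only_*` with the
strong/weak split keyed on the *other* axis; significant in neither →
`not_de`.

The strong/weak band is read as $|L2FC| < 1$ on the relevant axes.  Scatter
legends of this kind describe the strong points as having "L2FC > 1 and
< −1", which we interpret as $|L2FC| > 1$ (points outside the weak band);
for shared-significant points the weak class requires both axes weak, which
is forced by the definition of the either-significant weak (magenta) class.
The boundary $|L2FC| = 1$ is assigned to the strong class.  Whether the
original figures keyed the shared split on one axis or both is not stated
unambiguously; the rule here is documented as the package's choice, not
asserted as the authors' intent.

Correlations are Pearson's r over the **union** subset (significant in at
least one table — all coloured points) or the **shared** subset (significant
in both — the red/burgundy points); regressions are ordinary least squares
of y on x, fitted on the shared subset by default, with $R^2$ equal to the
squared shared-subset correlation by construction.
`outlier_sensitivity()` refits after dropping points beyond $\pm 20$ L2FC
(configurable): a handful of extreme fold changes, an artefact of
fold-change estimation when control replicates are highly variable, can
drag an otherwise near-unit slope well below 1.  `sign_concordance()`
reports, over genes significant in all k tables, the fraction whose k fold
changes share one sign; a zero L2FC breaks concordance (the conservative
reading).  `nestedness_fraction()` and `discordant_count()` cover the
remaining set-level summaries.

## The synthetic-data generator

`gen_de_tables()` emulates the three candidate regimes over a shared gene
namespace.  Each TF's universe is a nested prefix of a common expressed
pool (most expressed genes are common to all contrasts in practice);
`n_unexpressed` additional genes sit below the expression threshold with
`NA` padj.  DEG sets are drawn uniformly without replacement
(**independent**), without any overlap (**disjoint**), or with
$\mathrm{round}(\rho D)$ genes from a common core of `core_size` genes and
the remainder uniformly from the rest of the TF's universe
(**constrained**).

Drawing the constrained remainder from the whole universe minus the TF's
own core picks — rather than from strictly outside the core — is a
deliberate design choice: it makes the regime continuous in $\rho$ and
*exactly* the independent regime at $\rho = 0$, so the null calibration of
the overlap CI can be exercised through the same code path.  (Excluding the
entire core from the remainder would shrink the effective sampling frame to
$N - \mathrm{core}$ for every TF and inflate pairwise overlap above the
independent expectation even at $\rho = 0$.)  At $\rho = 0.8$, $D = 1000$,
$N = 10000$, core $= 1500$ the expected pairwise overlap is
$\approx 447$ against an independent expectation of 100.

Effect sizes follow a shared-plus-specific decomposition: a DEG's L2FC is
$g_\text{gene} + e_{\text{tf},\text{gene}}$ with
$g \sim \mathcal{N}(0, \sigma_g^2)$ shared across TFs and
$e \sim \mathcal{N}(0, \sigma_e^2)$ TF-specific, so the expected
shared-subset Pearson correlation between two TFs is
$\sigma_g^2 / (\sigma_g^2 + \sigma_e^2)$ — the parameter-recovery target
used in the tests (defaults $\sigma_g = 1$, $\sigma_e = 0.5$, hence 0.8).
Non-DEG L2FCs are $\mathcal{N}(0, 0.2)$ noise; the 0.2 is a configurable
convention, since no effect-size distribution for real non-DEGs is implied
by the method.  Adjusted p-values are synthesized directly —
$\mathrm{U}(0, \alpha)$ for DEGs, $\mathrm{U}(\alpha, 1)$ otherwise — so
`deg_set()` recovers the configured counts exactly; the pipeline's inputs
are DE tables, and re-implementing a DE model to generate them would test
the wrong thing.  `na_rate` sets L2FC cells (only) missing at random,
mirroring where NA exclusion bites downstream.  Base means are
$1 + \mathrm{lognormal}(\log 50, 1.5)$ for expressed genes, which straddles
the 1–10 decade where real analyses still call DEGs.

What the generator does *not* emulate: count-level noise propagated through
a DE fit (padj and L2FC are drawn, not estimated), batch structure,
correlated significance between near-threshold genes, and the
extreme-fold-change artefact (covered instead by a constructed fixture in
the concordance tests).  Passing tests therefore demonstrate correctness of
the statistics under the stated sampling models, not robustness to every
pathology of real RNA-seq.

## Count utilities

`normalize_to_max_total()` rescales every sample to the highest library
total — the convention for comparing control counts across analyses that
were normalized separately.  `counts_per_kb()` and `expression_ratio()`
implement the transgene-vs-endogenous abundance comparison: replicate
counts divided by transcript length in kb, ratio of means, reported at two
significant figures (round-half-even) with full precision retained.
Whether published ratios of this kind were computed from rounded or
unrounded per-replicate means is generally unknowable from a printed table;
the package computes from whatever precision it is given and does not force
agreement (`signif2()` is applied to the quotient of the supplied means).

## Problem sizes and determinism

The simulation-heavy checks run at the sizes the statistics are designed
for: universes of 10,000 genes, DEG sets of 500–5,000, 1,000 Monte Carlo
replicates per comparison, 100–200 generator runs for calibration and
separability — sizes chosen so that binomial/sampling tolerances
(±4 percentage points on CI coverage, ±0.05 on recovered correlations) are
comfortably resolvable.  Every random step is reproducible: generators and
reports take explicit seeds, sub-seeds are derived deterministically, and
all functions restore the caller's RNG state.  Pipeline outputs regenerate
bit-identically from (inputs, configuration, seed).

## Known limitations

* The analytic k-way expectation extends the pairwise product-of-fractions
  formula; for unequal universes it is a convention (mean weighting), and
  the report flags where it diverges from the exact resampling expectation.
* Observed-table reproduction of published overlap tables requires the
  original DE outputs; the package reproduces the machinery and its
  calibration, and the report *format* (57 comparison rows for six sets),
  not the printed per-row values.
* The order-statistic CI is discrete: with inclusive integer bounds its
  coverage is at least, and typically slightly above, the nominal 95%.
* No closed-form p-values for k-way overlap are provided; inference rests
  on the simulated CI and z-score, as in the method this package
  operationalises.
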