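# Small fixture builders used across test files.

# Minimal table: every argument recycled to the length of gene ids.
tiny_table <- function(gene_id, base_mean = 10, log2fc = 0, padj = 0.5,
                       pvalue = padj, label = "t") {
  n <- length(gene_id)
  de_table(gene_id, rep_len(base_mean, n), rep_len(log2fc, n),
           rep_len(pvalue, n), rep_len(padj, n), analysis_label = label)
}

# A de_table with randomly placed NAs, for round-trip and NA-rule tests.
random_table <- function(n = 50, label = "r", seed = 1) {
  set.seed(seed)
  lfc <- rnorm(n)
  lfc[sample(n, ceiling(n / 10))] <- NA
  padj <- runif(n)
  padj[sample(n, ceiling(n / 10))] <- NA
  de_table(sprintf("gene%03d", seq_len(n)), rlnorm(n, log(5), 2), lfc,
           pvalue = padj * 0.7, padj = padj, analysis_label = label)
}

# Paired-table fixture with exact L2FC/padj control: `spec` is a data frame
# with columns x_l2fc, y_l2fc, x_padj, y_padj (NA allowed).
paired_fixture <- function(spec) {
  n <- nrow(spec)
  ids <- sprintf("p%03d", seq_len(n))
  list(x = de_table(ids, 10, spec$x_l2fc, spec$x_padj, spec$x_padj, "X"),
       y = de_table(ids, 10, spec$y_l2fc, spec$y_padj, spec$y_padj, "Y"))
}
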