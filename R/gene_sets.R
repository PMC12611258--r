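#' Gene sets: expressed universes and DEG sets
#'
#' A `gene_set` is a set of gene ids with its provenance: the analysis it came
#' from, whether it is an expressed-gene universe or a DEG set, and the
#' thresholds that defined it.  DEG sets additionally carry the universe they
#' were drawn from, which is the sampling frame for the overlap null.
#'
#' @param genes character vector of gene ids (de-duplicated).
#' @param analysis_label contrast label.
#' @param kind `"universe"` or `"deg"`.
#' @param base_mean_min,alpha thresholds recorded as provenance.
#' @param universe for `kind = "deg"`, the character vector of expressed genes
#'   the set was derived within.
#' @return An object of class `gene_set`.
#' @export
gene_set <- function(genes, analysis_label, kind = c("universe", "deg"),
                     base_mean_min = NA_real_, alpha = NA_real_,
                     universe = NULL) {
  kind <- match.arg(kind)
  genes <- unique(as.character(genes))
  if (kind == "deg" && !is.null(universe)) {
    .assert(all(genes %in% universe),
            "a DEG set must be a subset of its universe")
  }
  structure(list(genes = genes, analysis_label = as.character(analysis_label),
                 kind = kind,
                 thresholds = c(base_mean_min = base_mean_min, alpha = alpha),
                 universe = if (!is.null(universe)) unique(as.character(universe))),
            class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("gene_set '%s' (%s): %d genes%s\n", x$analysis_label, x$kind,
              length(x$genes),
              if (!is.null(x$universe))
                sprintf(" in a universe of %d", length(x$universe)) else ""))
  invisible(x)
}

#' @export
length.gene_set <- function(x) length(x$genes)

#' Expressed-gene universe of a DE analysis
#'
#' The universe is the set of genes considered expressed in one analysis:
#' those with base mean strictly greater than `base_mean_min`.  The default
#' threshold of 1 keeps every gene for which the DE machinery could call a
#' DEG, which matters when the question is the structure of a TF-dependent
#' transcriptome rather than the importance of individual genes.
#'
#' @param table a [de_table].
#' @param base_mean_min strict lower bound on base mean (default 1).
#' @return A `gene_set` of kind `"universe"`.
#' @export
expressed_universe <- function(table, base_mean_min = 1) {
  stopifnot(inherits(table, "de_table"))
  gene_set(table$gene_id[table$base_mean > base_mean_min],
           analysis_label = analysis_label(table), kind = "universe",
           base_mean_min = base_mean_min)
}

#' DEG set of a DE analysis
#'
#' Genes with a present adjusted p-value strictly below `alpha`, intersected
#' with the expressed universe.  Genes whose `padj` is `NA` (filtered out by
#' the DE analysis) are never DEGs, though they may still be in the universe.
#'
#' @param table a [de_table].
#' @param alpha significance threshold on `padj`, in (0, 1); default 0.05.
#' @param universe the [expressed_universe()] of the same table; computed with
#'   its default threshold when omitted.
#' @return A `gene_set` of kind `"deg"` carrying its universe.
#' @export
deg_set <- function(table, alpha = 0.05, universe = NULL) {
  stopifnot(inherits(table, "de_table"))
  .assert(is.numeric(alpha) && length(alpha) == 1 && alpha > 0 && alpha < 1,
          "alpha must lie strictly between 0 and 1")
  if (is.null(universe)) universe <- expressed_universe(table)
  stopifnot(inherits(universe, "gene_set"), universe$kind == "universe")
  hits <- table$gene_id[!is.na(table$padj) & table$padj < alpha]
  gene_set(intersect(hits, universe$genes),
           analysis_label = analysis_label(table), kind = "deg",
           base_mean_min = universe$thresholds[["base_mean_min"]],
           alpha = alpha, universe = universe$genes)
}
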