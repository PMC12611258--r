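#' Count matrices
#'
#' A light container for a genes-by-samples matrix of non-negative counts,
#' optionally with per-gene transcript lengths in kilobases (used for
#' counts/kb normalization of transgene abundance estimates).
#'
#' @param counts numeric matrix, genes in rows, samples in columns; row and
#'   column names are the gene ids and sample labels.
#' @param lengths_kb optional named numeric vector of strictly positive
#'   transcript lengths (kb), names covering the row names of `counts`.
#' @return An object of class `count_matrix`.
#' @export
count_matrix <- function(counts, lengths_kb = NULL) {
  counts <- as.matrix(counts)
  .assert(!is.null(rownames(counts)) && !is.null(colnames(counts)),
          "counts must have gene row names and sample column names")
  .assert(all(counts >= 0), "counts must be non-negative")
  if (!is.null(lengths_kb)) {
    .assert(all(rownames(counts) %in% names(lengths_kb)),
            "lengths_kb must cover every gene in counts")
    lengths_kb <- lengths_kb[rownames(counts)]
    .assert(all(lengths_kb > 0), "transcript lengths must be > 0")
  }
  structure(list(counts = counts, lengths_kb = lengths_kb),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d samples%s\n", nrow(x$counts),
              ncol(x$counts),
              if (!is.null(x$lengths_kb)) " (with transcript lengths)" else ""))
  invisible(x)
}

#' Read a count matrix from TSV
#'
#' Genes in rows (first column = gene id), samples in columns.  An optional
#' two-column lengths table (`gene_id`, `length_kb`) supplies transcript
#' lengths.
#'
#' @param path TSV file of counts.
#' @param lengths_path optional TSV with columns `gene_id` and `length_kb`.
#' @return A [count_matrix].
#' @export
read_count_matrix <- function(path, lengths_path = NULL) {
  .assert(file.exists(path), "file not found: ", path)
  tab <- utils::read.table(path, header = TRUE, sep = "\t", row.names = 1,
                           check.names = FALSE)
  lengths <- NULL
  if (!is.null(lengths_path)) {
    lt <- utils::read.table(lengths_path, header = TRUE, sep = "\t",
                            check.names = FALSE)
    lengths <- stats::setNames(as.numeric(lt$length_kb),
                               as.character(lt$gene_id))
  }
  count_matrix(as.matrix(tab), lengths_kb = lengths)
}

#' Normalize samples to the highest library total
#'
#' Every sample's counts are scaled by (max sample total) / (that sample's
#' total), so all per-sample totals equal the maximum total afterwards and the
#' deepest sample is unchanged.  This puts control samples shared across
#' several DE analyses on one common scale, which per-analysis normalization
#' does not.
#'
#' @param m a [count_matrix] with at least one sample.
#' @return A [count_matrix] with equal per-sample totals.
#' @export
normalize_to_max_total <- function(m) {
  stopifnot(inherits(m, "count_matrix"))
  .assert(ncol(m$counts) >= 1, "need at least one sample")
  totals <- colSums(m$counts)
  zero <- colnames(m$counts)[totals == 0]
  .assert(length(zero) == 0,
          "sample(s) with zero total counts: ", paste(zero, collapse = ", "))
  scaled <- sweep(m$counts, 2, max(totals) / totals, `*`)
  count_matrix(scaled, lengths_kb = m$lengths_kb)
}

#' Length-normalized counts (counts/kb)
#'
#' Divides a count by the transcript length in kilobases, so that abundance
#' comparisons between transcripts of different lengths (e.g. a UAS transgene
#' versus the endogenous locus) are not confounded by length.
#'
#' @param count non-negative numeric vector of counts.
#' @param length_kb strictly positive length(s) in kb.
#' @return `count / length_kb`.
#' @export
counts_per_kb <- function(count, length_kb) {
  .assert(all(length_kb > 0), "length_kb must be > 0")
  count / length_kb
}

#' Transgene / endogenous expression ratio
#'
#' Ratio of mean transgene abundance to mean endogenous abundance, both in
#' counts/kb across replicates.  The full-precision ratio is returned with the
#' two-significant-figure rounding (the precision such ratios are reported at)
#' attached as `attr(, "rounded")`.
#'
#' @param uas_counts_per_kb replicate counts/kb for the UAS transgene.
#' @param endo_counts_per_kb replicate counts/kb for the endogenous locus.
#' @return Numeric scalar (full precision) with attribute `rounded`.
#' @examples
#' r <- expression_ratio(310, 170)
#' attr(r, "rounded")  # 1.8
#' @export
expression_ratio <- function(uas_counts_per_kb, endo_counts_per_kb) {
  .assert(length(uas_counts_per_kb) > 0 && length(endo_counts_per_kb) > 0,
          "both replicate lists must be nonempty")
  endo_mean <- mean(endo_counts_per_kb)
  .assert(endo_mean > 0, "undefined ratio: endogenous mean is 0")
  ratio <- mean(uas_counts_per_kb) / endo_mean
  structure(ratio, rounded = signif2(ratio))
}
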