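#' Differential-expression result tables
#'
#' A `de_table` holds the per-gene statistics of one differential-expression
#' contrast (typically one TF-versus-control DESeq2 analysis): gene id, base
#' mean (mean normalized count across samples), log2 fold change (L2FC),
#' p-value and BH-adjusted p-value.  Any of `log2fc`, `pvalue`, `padj` may be
#' `NA` (DESeq2 reports `NA` for genes it filters out); `base_mean` must be a
#' non-negative number for every row.
#'
#' @param gene_id character vector of unique gene identifiers.
#' @param base_mean non-negative numeric vector.
#' @param log2fc numeric vector, `NA` allowed.
#' @param pvalue,padj numeric vectors in `[0, 1]`, `NA` allowed.
#' @param analysis_label single string naming the contrast (e.g. `"BAB1"`).
#' @return A data frame of class `de_table` with columns `gene_id`,
#'   `base_mean`, `log2fc`, `pvalue`, `padj` and attribute `analysis_label`.
#' @examples
#' de_table(c("a", "b"), c(10, 0.5), c(1.2, NA), c(0.001, NA), c(0.01, NA),
#'          analysis_label = "demo")
#' @export
de_table <- function(gene_id, base_mean, log2fc = NA_real_, pvalue = NA_real_,
                     padj = NA_real_, analysis_label = "analysis") {
  n <- length(gene_id)
  tab <- data.frame(gene_id = as.character(gene_id),
                    base_mean = rep_len(as.numeric(base_mean), n),
                    log2fc = rep_len(as.numeric(log2fc), n),
                    pvalue = rep_len(as.numeric(pvalue), n),
                    padj = rep_len(as.numeric(padj), n),
                    stringsAsFactors = FALSE)
  validate_de_table(tab, analysis_label)
}

validate_de_table <- function(tab, analysis_label) {
  dup <- tab$gene_id[duplicated(tab$gene_id)]
  .assert(length(dup) == 0,
          "duplicate gene_id in table '", analysis_label, "': ",
          paste(unique(dup), collapse = ", "))
  .assert(all(!is.na(tab$base_mean) & tab$base_mean >= 0),
          "base_mean must be non-negative and non-missing")
  for (col in c("pvalue", "padj")) {
    v <- tab[[col]]
    .assert(all(is.na(v) | (v >= 0 & v <= 1)),
            col, " must lie in [0, 1] where present")
  }
  attr(tab, "analysis_label") <- as.character(analysis_label)
  class(tab) <- c("de_table", "data.frame")
  tab
}

#' @export
print.de_table <- function(x, ...) {
  cat(sprintf("de_table '%s': %d genes (%d with padj, %d with L2FC)\n",
              analysis_label(x), nrow(x), sum(!is.na(x$padj)),
              sum(!is.na(x$log2fc))))
  NextMethod()
}

#' @rdname de_table
#' @param x a `de_table`.
#' @export
analysis_label <- function(x) attr(x, "analysis_label", exact = TRUE)

# Accepted header aliases, DESeq2 export dialects vary.
.col_aliases <- list(
  gene_id = c("gene_id", "gene", "geneid", "id", "row.names"),
  base_mean = c("basemean", "base_mean"),
  log2fc = c("log2foldchange", "log2fc", "lfc"),
  pvalue = c("pvalue", "p_value", "pval"),
  padj = c("padj", "p_adj", "qvalue")
)

.match_column <- function(header, canonical, extra_aliases = NULL) {
  aliases <- c(.col_aliases[[canonical]], tolower(extra_aliases))
  which(tolower(header) %in% aliases)[1]
}

#' Read a differential-expression result table
#'
#' Reads a DESeq2-dialect CSV/TSV result file.  The header must contain (under
#' any accepted alias) baseMean, log2FoldChange and padj columns; a pvalue
#' column is optional.  The gene id is taken from a recognised id column or,
#' failing that, from the first column.  `"NA"` and empty cells become missing
#' values; row order is preserved; extra columns (lfcSE, stat, ...) are
#' ignored.
#'
#' @param path path to a delimited text file.
#' @param delimiter field separator; default guesses `"\t"` for `.tsv`/`.txt`
#'   files and `","` otherwise.
#' @param aliases optional named list mapping canonical column names
#'   (`gene_id`, `base_mean`, `log2fc`, `pvalue`, `padj`) to extra header
#'   aliases, e.g. `list(log2fc = "lfc_shrunk")`.
#' @param analysis_label label for the contrast; default is the file name
#'   without extension.
#' @return A [de_table].
#' @seealso [write_de_table()] for the exact-round-trip writer.
#' @export
read_de_table <- function(path, delimiter = NULL, aliases = NULL,
                          analysis_label = NULL) {
  .assert(file.exists(path), "file not found: ", path)
  if (is.null(delimiter)) {
    delimiter <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  }
  raw <- utils::read.table(path, header = TRUE, sep = delimiter,
                           na.strings = c("NA", ""), quote = "\"",
                           comment.char = "", check.names = FALSE,
                           colClasses = NA, stringsAsFactors = FALSE)
  header <- names(raw)
  idx <- list()
  for (canonical in c("gene_id", "base_mean", "log2fc", "pvalue", "padj")) {
    idx[[canonical]] <- .match_column(header, canonical, aliases[[canonical]])
  }
  if (is.na(idx$gene_id)) idx$gene_id <- 1L  # unnamed/unrecognised first column
  for (req in c("base_mean", "log2fc", "padj")) {
    .assert(!is.na(idx[[req]]),
            "format error in '", path, "': missing required column ", req,
            " (accepted aliases: ",
            paste(.col_aliases[[req]], collapse = ", "), ")")
  }
  grab <- function(i) if (is.na(i)) NA_real_ else as.numeric(raw[[i]])
  if (nrow(raw) == 0) {
    return(de_table(character(), numeric(), numeric(), numeric(), numeric(),
                    analysis_label = analysis_label %||%
                      sub("\\.[^.]*$", "", basename(path))))
  }
  de_table(gene_id = as.character(raw[[idx$gene_id]]),
           base_mean = grab(idx$base_mean),
           log2fc = grab(idx$log2fc),
           pvalue = grab(idx$pvalue),
           padj = grab(idx$padj),
           analysis_label = analysis_label %||%
             sub("\\.[^.]*$", "", basename(path)))
}

#' Write a differential-expression result table
#'
#' Writes a [de_table] as delimited text with canonical DESeq2-style headers
#' (`gene_id`, `baseMean`, `log2FoldChange`, `pvalue`, `padj`).  Missing values
#' are written as the token `"NA"`; the file round-trips exactly through
#' [read_de_table()].
#'
#' @param table a [de_table].
#' @param path output path.
#' @param delimiter field separator, default `","`.
#' @return `path`, invisibly.
#' @export
write_de_table <- function(table, path, delimiter = ",") {
  stopifnot(inherits(table, "de_table"))
  num <- function(v) ifelse(is.na(v), NA_character_, sprintf("%.17g", v))
  out <- data.frame(gene_id = table$gene_id,
                    baseMean = num(table$base_mean),
                    log2FoldChange = num(table$log2fc),
                    pvalue = num(table$pvalue),
                    padj = num(table$padj),
                    stringsAsFactors = FALSE)
  utils::write.table(out, file = path, sep = delimiter, quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}
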