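# Paired log2-fold-change analysis of two (or more) DE contrasts:
# scatter-point categories, correlations, regression, sign concordance.

#' Category levels of paired L2FC points
#'
#' Ordered levels of the scatter-point classification produced by
#' [classify_points()], mirroring the standard colour classes of paired-L2FC
#' scatter plots: red/burgundy (significant in both, strong/weak),
#' blue/light-blue (x only), green/light-green (y only), magenta (significant
#' in either but weak on both axes), grey (no significance), and the
#' NA-exclusion class.
#'
#' @export
l2fc_categories <- c("shared_strong", "shared_weak",
                     "x_only_strong", "x_only_weak",
                     "y_only_strong", "y_only_weak",
                     "either_weak_both", "not_de", "excluded_na")

#' Pair two DE tables by gene
#'
#' Inner join on gene id over the union of the two expressed universes.  A
#' gene with a missing L2FC in either table is retained with category
#' `excluded_na` but is dropped from every downstream statistic (the DE
#' machinery filtered it out in one analysis, so its pair is uninterpretable).
#' Significance flags are `padj < alpha` with missing `padj` counting as not
#' significant.
#'
#' @param x,y [de_table]s sharing a gene-id namespace.
#' @param alpha significance threshold (default 0.05).
#' @param base_mean_min universe threshold passed to [expressed_universe()].
#' @return Data frame with columns `gene_id`, `x_l2fc`, `y_l2fc`, `x_sig`,
#'   `y_sig`, `category` (only `excluded_na` assigned here; see
#'   [classify_points()]), plus attributes `x_label`/`y_label`.
#' @export
pair_tables <- function(x, y, alpha = 0.05, base_mean_min = 1) {
  stopifnot(inherits(x, "de_table"), inherits(y, "de_table"))
  ux <- expressed_universe(x, base_mean_min)$genes
  uy <- expressed_universe(y, base_mean_min)$genes
  keep <- union(ux, uy)
  common <- intersect(intersect(x$gene_id, y$gene_id), keep)
  .assert(length(common) > 0, "tables share no genes in the joint universe")
  xi <- x[match(common, x$gene_id), ]
  yi <- y[match(common, y$gene_id), ]
  pairs <- data.frame(gene_id = common,
                      x_l2fc = xi$log2fc, y_l2fc = yi$log2fc,
                      x_sig = !is.na(xi$padj) & xi$padj < alpha,
                      y_sig = !is.na(yi$padj) & yi$padj < alpha,
                      category = NA_character_,
                      stringsAsFactors = FALSE)
  pairs$category[is.na(pairs$x_l2fc) | is.na(pairs$y_l2fc)] <- "excluded_na"
  attr(pairs, "x_label") <- analysis_label(x)
  attr(pairs, "y_label") <- analysis_label(y)
  attr(pairs, "alpha") <- alpha
  pairs
}

#' Classify paired L2FC points into scatter categories
#'
#' Precedence: (1) genes significant in neither table are `not_de`;
#' (2) genes significant in both are `shared_weak` when both |L2FC| are below
#' `l2fc_thresh` and `shared_strong` otherwise; (3) genes significant in
#' exactly one table are `either_weak_both` when both |L2FC| are below the
#' threshold, and otherwise `x_only_strong`/`x_only_weak` (significant in x;
#' strong iff the *other* axis |y L2FC| is at or beyond the threshold) or the
#' y mirror.  The boundary |L2FC| = `l2fc_thresh` counts as strong.
#' Genes already marked `excluded_na` are left untouched.
#'
#' @param pairs output of [pair_tables()].
#' @param l2fc_thresh strong/weak threshold on |L2FC| (default 1).
#' @return `pairs` with `category` filled in (factor over [l2fc_categories]).
#' @export
classify_points <- function(pairs, l2fc_thresh = 1) {
  t <- l2fc_thresh
  ax <- abs(pairs$x_l2fc)
  ay <- abs(pairs$y_l2fc)
  cat <- pairs$category
  open <- is.na(cat)
  both_weak <- ax < t & ay < t
  cat[open & !pairs$x_sig & !pairs$y_sig] <- "not_de"
  cat[open & pairs$x_sig & pairs$y_sig] <-
    ifelse(both_weak[open & pairs$x_sig & pairs$y_sig],
           "shared_weak", "shared_strong")
  xo <- open & pairs$x_sig & !pairs$y_sig
  cat[xo] <- ifelse(both_weak[xo], "either_weak_both",
                    ifelse(ay[xo] >= t, "x_only_strong", "x_only_weak"))
  yo <- open & !pairs$x_sig & pairs$y_sig
  cat[yo] <- ifelse(both_weak[yo], "either_weak_both",
                    ifelse(ax[yo] >= t, "y_only_strong", "y_only_weak"))
  pairs$category <- factor(cat, levels = l2fc_categories)
  pairs
}

# rows usable for statistics: L2FC present in both tables
.usable <- function(pairs) {
  pairs[!(is.na(pairs$x_l2fc) | is.na(pairs$y_l2fc)), , drop = FALSE]
}

.subset_pairs <- function(pairs, subset = c("union", "shared")) {
  subset <- match.arg(subset)
  p <- .usable(pairs)
  if (subset == "union") p[p$x_sig | p$y_sig, , drop = FALSE]
  else p[p$x_sig & p$y_sig, , drop = FALSE]
}

#' Pearson correlation over a significance subset
#'
#' Pearson's r of the paired L2FCs over genes significant in at least one
#' table (`"union"`, all coloured points of the scatter) or in both tables
#' (`"shared"`, the red/burgundy points).  Degenerate subsets (under three
#' points or zero variance on an axis) give flagged `NA`.
#'
#' @param pairs output of [pair_tables()]/[classify_points()].
#' @param subset `"union"` or `"shared"`.
#' @return Pearson r, or `NA` with attribute `undefined = TRUE`.
#' @export
pearson_subset <- function(pairs, subset = c("union", "shared")) {
  p <- .subset_pairs(pairs, subset)
  if (nrow(p) < 3 || stats::sd(p$x_l2fc) == 0 || stats::sd(p$y_l2fc) == 0) {
    return(structure(NA_real_, undefined = TRUE))
  }
  stats::cor(p$x_l2fc, p$y_l2fc)
}

#' OLS regression of y L2FC on x L2FC
#'
#' Ordinary least squares over the chosen subset (default the shared
#' red/burgundy points, the convention for regressions of paired DE effect
#' sizes).  R-squared equals the squared Pearson correlation on the same
#' points.
#'
#' @inheritParams pearson_subset
#' @return List with `slope`, `intercept`, `r_squared`, `n`; flagged `NA`s
#'   when the subset is degenerate.
#' @export
ols_fit <- function(pairs, subset = c("shared", "union")) {
  subset <- match.arg(subset)
  p <- .subset_pairs(pairs, subset)
  if (nrow(p) < 3 || stats::sd(p$x_l2fc) == 0) {
    return(structure(list(slope = NA_real_, intercept = NA_real_,
                          r_squared = NA_real_, n = nrow(p)),
                     undefined = TRUE))
  }
  fit <- stats::lm(y_l2fc ~ x_l2fc, data = p)
  r2 <- if (stats::sd(p$y_l2fc) == 0) 1 else
    stats::cor(p$x_l2fc, p$y_l2fc)^2
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = r2,
       n = nrow(p))
}

#' Sensitivity of the regression to extreme fold changes
#'
#' A handful of points with very large |L2FC| (an artefact of fold-change
#' estimation when control replicates are highly variable) can drag the slope
#' away from 1.  This refits after removing points with |x| or |y| beyond
#' `extreme_thresh` and reports both fits plus the removed gene ids.
#'
#' @inheritParams pearson_subset
#' @param extreme_thresh |L2FC| beyond which a point is deemed extreme
#'   (default 20).
#' @return List with `fit_all`, `fit_trimmed` (both as [ols_fit()] results)
#'   and `removed` (character vector of gene ids).
#' @export
outlier_sensitivity <- function(pairs, subset = c("shared", "union"),
                                extreme_thresh = 20) {
  subset <- match.arg(subset)
  p <- .subset_pairs(pairs, subset)
  extreme <- abs(p$x_l2fc) > extreme_thresh | abs(p$y_l2fc) > extreme_thresh
  trimmed <- pairs[!pairs$gene_id %in% p$gene_id[extreme], , drop = FALSE]
  list(fit_all = ols_fit(pairs, subset),
       fit_trimmed = ols_fit(trimmed, subset),
       removed = p$gene_id[extreme])
}

#' Sign concordance across k DE tables
#'
#' Over genes significant (`padj < alpha`) in all k tables with no missing
#' L2FC, the fraction whose k fold changes are all positive or all negative.
#' A zero L2FC breaks concordance.  Under fully independent signs the
#' expected fraction is `2^(1-k)`.
#'
#' @param tables list of k >= 2 [de_table]s.
#' @param alpha significance threshold (default 0.05).
#' @return Fraction in `[0, 1]`, or `NA` flagged `undefined` when no gene is
#'   eligible; the eligible-gene count is attached as `attr(, "n")`.
#' @export
sign_concordance <- function(tables, alpha = 0.05) {
  .assert(length(tables) >= 2, "need at least 2 tables")
  ids <- Reduce(intersect, lapply(tables, function(t) {
    t$gene_id[!is.na(t$padj) & t$padj < alpha & !is.na(t$log2fc)]
  }))
  if (length(ids) == 0) return(structure(NA_real_, undefined = TRUE, n = 0L))
  l2fc <- vapply(tables, function(t) t$log2fc[match(ids, t$gene_id)],
                 numeric(length(ids)))
  l2fc <- matrix(l2fc, nrow = length(ids))
  conc <- rowSums(l2fc > 0) == ncol(l2fc) | rowSums(l2fc < 0) == ncol(l2fc)
  structure(mean(conc), n = length(ids))
}

#' Nestedness of one DEG set within another
#'
#' Fraction of the inner set contained in the outer set,
#' `|inner intersect outer| / |inner|` -- e.g. how much of a downstream TF's
#' DEG set sits inside the upstream TF's DEG set.
#'
#' @param inner,outer [gene_set]s or character vectors; `inner` nonempty.
#' @return Fraction in `[0, 1]`, or flagged `NA` for an empty inner set.
#' @export
nestedness_fraction <- function(inner, outer) {
  gi <- if (inherits(inner, "gene_set")) inner$genes else as.character(inner)
  go <- if (inherits(outer, "gene_set")) outer$genes else as.character(outer)
  if (length(gi) == 0) return(structure(NA_real_, undefined = TRUE))
  length(intersect(gi, go)) / length(gi)
}

#' Count discordantly regulated shared genes
#'
#' Among genes significant in both tables (with both L2FCs present), the
#' number regulated in opposite directions: up with one TF and down with the
#' other.
#'
#' @param pairs output of [pair_tables()]/[classify_points()].
#' @return Integer count.
#' @export
discordant_count <- function(pairs) {
  p <- .subset_pairs(pairs, "shared")
  sum((p$x_l2fc > 0 & p$y_l2fc < 0) | (p$x_l2fc < 0 & p$y_l2fc > 0))
}

#' Per-gene mean L2FC over several tables
#'
#' Arithmetic mean of the log2 fold changes over tables, for genes present in
#' all of them with no missing L2FC -- used to plot several nonresident-TF
#' responses against one resident TF on a single axis.
#'
#' @param tables list of >= 2 [de_table]s.
#' @return Named numeric vector, gene id to mean L2FC.
#' @export
average_l2fc <- function(tables) {
  .assert(length(tables) >= 2, "need at least 2 tables")
  ids <- Reduce(intersect, lapply(tables, function(t) {
    t$gene_id[!is.na(t$log2fc)]
  }))
  if (length(ids) == 0) return(stats::setNames(numeric(0), character(0)))
  l2fc <- vapply(tables, function(t) t$log2fc[match(ids, t$gene_id)],
                 numeric(length(ids)))
  l2fc <- matrix(l2fc, nrow = length(ids))
  stats::setNames(rowMeans(l2fc), ids)
}

#' Concordance summary for one pair of DE tables
#'
#' Bundles the per-pair statistics: category counts, union and shared Pearson
#' correlations, the shared-subset regression, and the discordant-gene count.
#'
#' @param x,y [de_table]s.
#' @param alpha,base_mean_min,l2fc_thresh thresholds (defaults 0.05, 1, 1).
#' @param extreme_thresh passed to [outlier_sensitivity()].
#' @return List of class `concordance_summary`.
#' @export
concordance_summary <- function(x, y, alpha = 0.05, base_mean_min = 1,
                                l2fc_thresh = 1, extreme_thresh = 20) {
  pairs <- classify_points(pair_tables(x, y, alpha, base_mean_min),
                           l2fc_thresh)
  structure(list(
    x_label = attr(pairs, "x_label"),
    y_label = attr(pairs, "y_label"),
    n_category = table(pairs$category),
    pearson_union = as.numeric(pearson_subset(pairs, "union")),
    pearson_shared = as.numeric(pearson_subset(pairs, "shared")),
    regression = ols_fit(pairs, "shared"),
    outliers = outlier_sensitivity(pairs, "shared", extreme_thresh),
    discordant_shared = discordant_count(pairs),
    pairs = pairs), class = "concordance_summary")
}

#' @export
print.concordance_summary <- function(x, ...) {
  cat(sprintf("concordance %s vs %s: r(union) = %.3f, r(shared) = %.3f\n",
              x$x_label, x$y_label, x$pearson_union, x$pearson_shared))
  cat(sprintf("  shared regression: slope %.3f, intercept %.3f, R^2 %.3f (n = %d)\n",
              x$regression$slope, x$regression$intercept,
              x$regression$r_squared, x$regression$n))
  cat(sprintf("  discordant shared genes: %d\n", x$discordant_shared))
  print(x$n_category)
  invisible(x)
}
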