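# Multi-way DEG-set overlap: observed intersections, analytic expectation
# under independence, Monte Carlo null, order-statistic CI and z-score.

#' k-way intersection of DEG sets
#'
#' Genes present in every listed set.  This is the "shared genes" quantity of
#' an overlap report row: a plain intersection, not an exclusive Venn region,
#' so adding a set to a comparison can never increase the count.
#'
#' @param deg_sets list of at least two [gene_set]s (or character vectors).
#' @return List with `count` and `genes`.
#' @export
intersect_k <- function(deg_sets) {
  .assert(length(deg_sets) >= 2, "need at least 2 sets to intersect")
  members <- lapply(deg_sets, function(s) if (inherits(s, "gene_set")) s$genes else as.character(s))
  shared <- Reduce(intersect, members)
  list(count = length(shared), genes = shared)
}

#' Exclusive Venn-region counts
#'
#' Partitions the union of up to six gene sets into exclusive regions: each
#' gene is counted in the region of exactly the sets that contain it.  Region
#' counts therefore sum to the union size, and summing all regions containing
#' a given label recovers that set's size.
#'
#' @param deg_sets named list of 2--6 [gene_set]s or character vectors; names
#'   default to the sets' analysis labels.
#' @return Named integer vector over all `2^k - 1` nonempty label subsets
#'   (labels joined by `","`), zeros included.
#' @export
venn_region_counts <- function(deg_sets) {
  k <- length(deg_sets)
  .assert(k >= 2, "need at least 2 sets")
  .assert(k <= 6, "Venn regions supported for at most 6 sets (got ", k, ")")
  labels <- names(deg_sets) %||% vapply(deg_sets, function(s)
    if (inherits(s, "gene_set")) s$analysis_label else NA_character_, "")
  if (is.null(names(deg_sets)) || any(!nzchar(labels)) || anyNA(labels))
    .assert(FALSE, "sets must be named or carry analysis labels")
  members <- lapply(deg_sets, function(s) if (inherits(s, "gene_set")) s$genes else as.character(s))
  all_genes <- unique(unlist(members))
  # membership pattern per gene, encoded as a bit mask over the k sets
  mask <- integer(length(all_genes))
  for (i in seq_len(k)) {
    mask <- mask + bitwShiftL(as.integer(all_genes %in% members[[i]]), i - 1L)
  }
  region_label <- function(bits) {
    paste(labels[bitwAnd(bitwShiftR(bits, seq_len(k) - 1L), 1L) == 1L],
          collapse = ",")
  }
  out <- integer(2^k - 1)
  names(out) <- vapply(seq_len(2^k - 1), region_label, "")
  tab <- table(mask)
  out[as.integer(names(tab))] <- as.integer(tab)
  out
}

#' Analytic expected overlap under independence
#'
#' The expected number of genes shared by k independent DEG sets, computed as
#' the product of the per-analysis DEG fractions `D_i / N_i` multiplied by the
#' mean universe size: for two sets, `(D1/N1)(D2/N2) * mean(N1, N2)`.  The
#' k-way case extends the pairwise formula with the product over all k
#' fractions.  When universes differ in size this mean-weighted form deviates
#' from the exact expectation of the resampling scheme, which weights by the
#' smallest universe (see [overlap_report()], which computes both and flags
#' divergence).
#'
#' @param deg_counts integer vector of DEG-set sizes `D_i`.
#' @param universe_sizes integer vector of universe sizes `N_i`.
#' @return Expected shared-gene count (real).
#' @export
expected_overlap <- function(deg_counts, universe_sizes) {
  .check_overlap_args(deg_counts, universe_sizes)
  prod(deg_counts / universe_sizes) * mean(universe_sizes)
}

# Exact expectation of the integer-labeling resampling scheme: only labels up
# to min(N_i) can be shared, each with probability prod(D_i/N_i).
.expected_overlap_exact <- function(deg_counts, universe_sizes) {
  prod(deg_counts / universe_sizes) * min(universe_sizes)
}

.check_overlap_args <- function(deg_counts, universe_sizes) {
  .assert(length(deg_counts) == length(universe_sizes) && length(deg_counts) >= 2,
          "deg_counts and universe_sizes must have equal length >= 2")
  .assert(all(universe_sizes > 0), "universe sizes must be positive")
  .assert(all(deg_counts >= 0 & deg_counts <= universe_sizes),
          "each DEG count must satisfy 0 <= D_i <= N_i")
}

#' Monte Carlo null distribution of the shared-gene count
#'
#' Per replicate, each of the k analyses draws `D_i` distinct integer labels
#' uniformly from `{1..N_i}` (its own expressed-gene universe) and the number
#' of labels common to all k draws is recorded.  The scheme identifies the
#' low-indexed labels across analyses, exactly as in per-analysis resampling
#' of separately determined universes; with equal universes and k = 2 the
#' replicate count is hypergeometric.
#'
#' @inheritParams expected_overlap
#' @param n_reps number of replicates (default 1000).
#' @param seed integer seed; the caller's RNG state is untouched.
#' @return Object of class `simulated_null`: list with `samples` (integer
#'   vector of length `n_reps`), `mean`, and `sd` (sample sd, n-1
#'   denominator).
#' @export
simulate_overlap <- function(deg_counts, universe_sizes, n_reps = 1000,
                             seed = NULL) {
  .check_overlap_args(deg_counts, universe_sizes)
  .assert(n_reps >= 1, "n_reps must be >= 1")
  k <- length(deg_counts)
  samples <- .with_seed(seed, {
    counts <- integer(n_reps)
    for (r in seq_len(n_reps)) {
      common <- sample.int(universe_sizes[1], deg_counts[1])
      for (i in 2:k) {
        draw <- sample.int(universe_sizes[i], deg_counts[i])
        common <- common[match(common, draw, nomatch = 0L) > 0L]
        if (length(common) == 0) break
      }
      counts[r] <- length(common)
    }
    counts
  })
  structure(list(samples = samples, mean = mean(samples),
                 sd = stats::sd(samples)),
            class = "simulated_null")
}

#' @export
print.simulated_null <- function(x, ...) {
  cat(sprintf("simulated_null: %d replicates, mean %.3g, sd %.3g\n",
              length(x$samples), x$mean, x$sd))
  invisible(x)
}

#' Order-statistic 95% confidence interval
#'
#' The interval bounded by the k-th smallest and k-th largest replicate
#' values, with k = 25 at 1000 replicates (2.5% from each end, i.e. the 25th
#' numbers from both the lowest and highest simulated counts); in general
#' `k = max(1, round(0.025 * n_reps))`.  Bounds are inclusive.
#'
#' @param null a `simulated_null` from [simulate_overlap()], or a numeric
#'   vector of replicate counts.
#' @return Integer vector `c(ci_low, ci_high)`.
#' @export
ci95 <- function(null) {
  samples <- if (inherits(null, "simulated_null")) null$samples else null
  n <- length(samples)
  .assert(n >= 40,
          "need at least 40 replicates for the 2.5% order statistic; got ", n,
          " - increase n_reps")
  k <- max(1L, as.integer(round(0.025 * n)))
  s <- sort(samples)
  c(ci_low = s[k], ci_high = s[n - k + 1L])
}

#' Overlap z-score
#'
#' `(observed - simulated mean) / simulated sd`.  When the null is degenerate
#' (sd = 0) the z-score is undefined and `NA` is returned with attribute
#' `undefined = TRUE`; it is never reported as infinite.
#'
#' @param observed observed shared-gene count.
#' @param null a `simulated_null` (or any list with `mean` and `sd`).
#' @return Numeric scalar, or flagged `NA` when sd = 0.
#' @export
z_score <- function(observed, null) {
  if (!is.na(null$sd) && null$sd == 0) {
    return(structure(NA_real_, undefined = TRUE))
  }
  (observed - null$mean) / null$sd
}

#' Independence call from the simulated CI
#'
#' `"within"` iff `ci_low <= observed <= ci_high` (inclusive bounds);
#' `"above"` or `"below"` otherwise.  An observed count outside the CI rejects
#' the hypothesis that the DEG sets overlap only as much as independent draws
#' would.
#'
#' @param observed observed shared-gene count.
#' @param ci length-2 vector `(ci_low, ci_high)`.
#' @return `"within"`, `"above"`, or `"below"`.
#' @export
independence_call <- function(observed, ci) {
  .assert(ci[1] <= ci[2], "ci_low must be <= ci_high")
  if (observed > ci[2]) "above" else if (observed < ci[1]) "below" else "within"
}

#' Full overlap report over subsets of DEG sets
#'
#' One row per subset of 2..`max_order` DEG sets: observed shared count,
#' analytic expectation, Monte Carlo mean/sd, order-statistic 95% CI, z-score
#' and independence call.  Each subset gets a reproducible sub-seed derived
#' from `(seed, sorted labels)`, so adding comparisons never perturbs existing
#' rows.  Rows are ordered by subset size, then by label order.
#'
#' Two expectation columns are reported: `expected` (mean-universe weighting,
#' the convention of the published tables) and `expected_exact` (the exact
#' expectation of the resampling scheme, min-universe weighting); rows where
#' the two diverge by more than 5% are flagged in `expected_divergent`.
#'
#' @param deg_sets list of at least two `"deg"`-kind [gene_set]s carrying
#'   their universes.
#' @param max_order largest subset size to report (default: all sets).
#' @param n_reps Monte Carlo replicates per row (default 1000).
#' @param seed integer seed for the whole report.
#' @param universe_mode `"per-analysis"` (each analysis resamples within its
#'   own universe; the faithful scheme) or `"common"` (all analyses resample
#'   within the intersection of the universes).
#' @return A data frame of class `overlap_report`, one row per comparison,
#'   with the shared gene ids in the list column `shared_genes`.
#' @export
overlap_report <- function(deg_sets, max_order = length(deg_sets),
                           n_reps = 1000, seed = 1,
                           universe_mode = c("per-analysis", "common")) {
  universe_mode <- match.arg(universe_mode)
  k <- length(deg_sets)
  .assert(k >= 2, "need at least 2 DEG sets")
  .assert(max_order >= 2 && max_order <= k,
          "max_order must lie between 2 and the number of sets")
  for (s in deg_sets) {
    stopifnot(inherits(s, "gene_set"))
    .assert(s$kind == "deg" && !is.null(s$universe),
            "overlap_report needs deg-kind gene_sets carrying their universes")
  }
  labels <- vapply(deg_sets, function(s) s$analysis_label, "")
  .assert(!anyDuplicated(labels), "analysis labels must be unique")
  common_universe <- Reduce(intersect, lapply(deg_sets, function(s) s$universe))

  rows <- list()
  for (size in 2:max_order) {
    for (ix in utils::combn(k, size, simplify = FALSE)) {
      sub <- deg_sets[ix]
      sub_labels <- labels[ix]
      obs <- intersect_k(sub)
      D <- vapply(sub, function(s) length(s$genes), 0L)
      N <- if (universe_mode == "common") {
        rep(length(common_universe), size)
      } else {
        vapply(sub, function(s) length(s$universe), 0L)
      }
      sub_seed <- .subset_seed(seed, sub_labels)
      null <- simulate_overlap(pmin(D, N), N, n_reps = n_reps, seed = sub_seed)
      ci <- ci95(null)
      exp_mean <- expected_overlap(pmin(D, N), N)
      exp_exact <- .expected_overlap_exact(pmin(D, N), N)
      divergent <- exp_exact > 0 && abs(exp_mean - exp_exact) / exp_exact > 0.05
      z <- z_score(obs$count, null)
      rows[[length(rows) + 1L]] <- data.frame(
        comparison = paste(sub_labels, collapse = ","),
        order = size,
        shared = obs$count,
        expected = exp_mean,
        expected_exact = exp_exact,
        expected_divergent = divergent,
        ci_low = ci[["ci_low"]],
        ci_high = ci[["ci_high"]],
        simulated_mean = null$mean,
        simulated_sd = null$sd,
        z = as.numeric(z),
        z_undefined = isTRUE(attr(z, "undefined")),
        call = independence_call(obs$count, ci),
        n_reps = n_reps,
        seed = sub_seed,
        stringsAsFactors = FALSE)
      rows[[length(rows)]]$shared_genes <- I(list(obs$genes))
    }
  }
  report <- do.call(rbind, rows)
  rownames(report) <- NULL
  attr(report, "universe_mode") <- universe_mode
  attr(report, "run_seed") <- seed
  class(report) <- c("overlap_report", "data.frame")
  report
}

#' Write an overlap report as TSV
#'
#' Flat columns only; the `shared_genes` list column is dropped from the main
#' table and optionally written as a long-format gene-list TSV.
#'
#' @param report an [overlap_report()] result.
#' @param path output TSV path.
#' @param genes_path optional path for a two-column (`gene_id`, `comparison`)
#'   gene-list TSV.
#' @return `path`, invisibly.
#' @export
write_overlap_report <- function(report, path, genes_path = NULL) {
  flat <- report[setdiff(names(report), "shared_genes")]
  utils::write.table(flat, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(genes_path)) {
    genes <- do.call(rbind, lapply(seq_len(nrow(report)), function(i) {
      g <- report$shared_genes[[i]]
      if (length(g) == 0) return(NULL)
      data.frame(gene_id = g, comparison = report$comparison[i],
                 stringsAsFactors = FALSE)
    }))
    if (is.null(genes))
      genes <- data.frame(gene_id = character(), comparison = character())
    utils::write.table(genes, genes_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
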