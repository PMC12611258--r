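# End-to-end orchestration: tables -> universes/DEG sets -> overlap report +
# per-pair concordance summaries -> combined JSON report.

#' Run configuration for the full pipeline
#'
#' @param tables named list of [de_table]s, or a named character vector of
#'   file paths read with [read_de_table()].
#' @param alpha DEG threshold on padj (default 0.05).
#' @param base_mean_min expressed-universe threshold (default 1).
#' @param l2fc_thresh strong/weak scatter threshold (default 1).
#' @param extreme_thresh outlier-refit threshold (default 20).
#' @param n_reps Monte Carlo replicates per overlap row (default 1000).
#' @param max_order largest comparison order (default: all tables).
#' @param universe_mode `"per-analysis"` or `"common"` (see
#'   [overlap_report()]).
#' @param seed run seed.
#' @param out_dir output directory, created if needed; `NULL` for no files.
#' @return A list of class `run_config`.
#' @export
run_config <- function(tables, alpha = 0.05, base_mean_min = 1,
                       l2fc_thresh = 1, extreme_thresh = 20, n_reps = 1000,
                       max_order = NULL, universe_mode = "per-analysis",
                       seed = 1, out_dir = NULL) {
  if (is.character(tables)) {
    labels <- names(tables) %||% sub("\\.[^.]*$", "", basename(tables))
    tables <- mapply(function(p, lab) read_de_table(p, analysis_label = lab),
                     tables, labels, SIMPLIFY = FALSE)
    names(tables) <- labels
  }
  .assert(length(tables) >= 2, "need at least 2 input tables")
  labels <- vapply(tables, analysis_label, "")
  .assert(!anyDuplicated(labels), "analysis labels must be unique")
  names(tables) <- labels
  .assert(alpha > 0 && alpha < 1, "alpha must lie in (0, 1)")
  structure(list(tables = tables, alpha = alpha,
                 base_mean_min = base_mean_min, l2fc_thresh = l2fc_thresh,
                 extreme_thresh = extreme_thresh, n_reps = n_reps,
                 max_order = max_order %||% length(tables),
                 universe_mode = universe_mode, seed = seed,
                 out_dir = out_dir),
            class = "run_config")
}

.log_msg <- function(verbose, ...) {
  if (verbose) message(sprintf(...))
}

.prep_sets <- function(config, verbose) {
  lapply(config$tables, function(t) {
    u <- expressed_universe(t, config$base_mean_min)
    d <- deg_set(t, config$alpha, u)
    .log_msg(verbose, "[degoverlap] %s: %d expressed genes, %d DEGs",
             analysis_label(t), length(u), length(d))
    d
  })
}

#' Run the overlap stage and write its report
#'
#' Derives universes and DEG sets from every input table and writes the
#' overlap report TSV (plus per-comparison shared-gene lists).
#'
#' @param config a [run_config()].
#' @param verbose log sizes, seeds and thresholds to stderr (default TRUE).
#' @return The [overlap_report()] data frame, invisibly when files are
#'   written.
#' @export
run_overlap_command <- function(config, verbose = TRUE) {
  stopifnot(inherits(config, "run_config"))
  .log_msg(verbose,
           "[degoverlap] overlap: alpha %g, base_mean_min %g, n_reps %d, seed %d, universe %s",
           config$alpha, config$base_mean_min, config$n_reps, config$seed,
           config$universe_mode)
  sets <- .prep_sets(config, verbose)
  report <- overlap_report(sets, max_order = config$max_order,
                           n_reps = config$n_reps, seed = config$seed,
                           universe_mode = config$universe_mode)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_overlap_report(report,
                         file.path(config$out_dir, "overlap_report.tsv"),
                         file.path(config$out_dir, "overlap_genes.tsv"))
    return(invisible(report))
  }
  report
}

#' Run the concordance stage over all table pairs
#'
#' Every unordered pair of input tables is summarized; per-pair categorized
#' point TSVs and a Pearson matrix (union correlations in the lower triangle,
#' shared correlations in the upper, mirroring the published matrix layout)
#' are written when an output directory is configured.
#'
#' @inheritParams run_overlap_command
#' @return List with `summaries` (one `concordance_summary` per pair) and
#'   `pearson_matrix`.
#' @export
run_concordance_command <- function(config, verbose = TRUE) {
  stopifnot(inherits(config, "run_config"))
  labels <- names(config$tables)
  k <- length(labels)
  pearson <- matrix(NA_real_, k, k, dimnames = list(labels, labels))
  summaries <- list()
  for (ij in utils::combn(k, 2, simplify = FALSE)) {
    i <- ij[1]; j <- ij[2]
    s <- concordance_summary(config$tables[[i]], config$tables[[j]],
                             alpha = config$alpha,
                             base_mean_min = config$base_mean_min,
                             l2fc_thresh = config$l2fc_thresh,
                             extreme_thresh = config$extreme_thresh)
    key <- paste(labels[i], labels[j], sep = "_vs_")
    summaries[[key]] <- s
    pearson[j, i] <- s$pearson_union   # lower triangle: union of DEG sets
    pearson[i, j] <- s$pearson_shared  # upper triangle: shared DEGs
    .log_msg(verbose, "[degoverlap] %s: r(union) %.3f, r(shared) %.3f", key,
             s$pearson_union, s$pearson_shared)
  }
  out <- list(summaries = summaries, pearson_matrix = pearson)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    for (key in names(summaries)) {
      pairs <- summaries[[key]]$pairs
      utils::write.table(pairs, file.path(config$out_dir,
                                          paste0("pairs_", key, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    utils::write.table(cbind(analysis = rownames(pearson),
                             as.data.frame(pearson)),
                       file.path(config$out_dir, "pearson_matrix.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(out))
  }
  out
}

#' Run the full pipeline and write a combined JSON report
#'
#' Universes/DEG sets, then the overlap report, then all pairwise concordance
#' summaries, combined into one JSON document that echoes the configuration
#' and seed so any run can be regenerated bit-identically.
#'
#' @inheritParams run_overlap_command
#' @return The combined report as a list; written to
#'   `out_dir/combined_report.json` when an output directory is configured.
#' @export
run_full_pipeline <- function(config, verbose = TRUE) {
  stopifnot(inherits(config, "run_config"))
  overlap <- run_overlap_command(config, verbose = verbose)
  concord <- run_concordance_command(config, verbose = verbose)
  sets <- .prep_sets(config, verbose = FALSE)
  combined <- list(
    package_version = as.character(utils::packageVersion("degoverlap")),
    config = list(alpha = config$alpha, base_mean_min = config$base_mean_min,
                  l2fc_thresh = config$l2fc_thresh,
                  extreme_thresh = config$extreme_thresh,
                  n_reps = config$n_reps, max_order = config$max_order,
                  universe_mode = config$universe_mode, seed = config$seed,
                  labels = names(config$tables)),
    set_sizes = lapply(sets, function(s)
      list(degs = length(s$genes), universe = length(s$universe))),
    overlap = as.data.frame(overlap[setdiff(names(overlap), "shared_genes")]),
    concordance = lapply(concord$summaries, function(s) list(
      x_label = s$x_label, y_label = s$y_label,
      n_category = as.list(as.integer(s$n_category)) |>
        stats::setNames(names(s$n_category)),
      pearson_union = s$pearson_union, pearson_shared = s$pearson_shared,
      regression = s$regression,
      discordant_shared = s$discordant_shared)),
    pearson_matrix = concord$pearson_matrix)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(combined,
                         file.path(config$out_dir, "combined_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         na = "null")
  }
  invisible(combined)
}
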