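# Synthetic DE-table generator under three candidate regimes of multi-TF
# regulation, plus count-matrix and transgene fixtures and a brute-force
# enumeration oracle for the Monte Carlo overlap null.

#' Configuration of the synthetic regime generator
#'
#' Describes one simulated study: `n_tfs` DE contrasts over a shared gene
#' namespace, each with an expressed universe of `universe_size` genes and
#' `deg_count` DEGs, under one of three regimes:
#' \describe{
#'   \item{independent}{each TF's DEG set is drawn uniformly without
#'     replacement from its universe, independently of the others;}
#'   \item{disjoint}{DEG sets are drawn without any overlap (requires
#'     `sum(deg_count) <= universe_size`);}
#'   \item{constrained}{a common "core" of `core_size` genes exists and each
#'     TF draws `round(rho * deg_count)` of its DEGs from the core, with the
#'     remainder drawn uniformly from the rest of its universe (everything it
#'     has not already picked), so overlap far exceeds the independent
#'     expectation when `rho` is high and the regime reduces exactly to
#'     `independent` at `rho = 0`.}
#' }
#' A DEG's log2 fold change is `g_gene + e_tf,gene` with the gene-level effect
#' `g ~ Normal(0, sigma_g)` shared across TFs and `e ~ Normal(0, sigma_e)`
#' TF-specific, so the expected shared-subset Pearson correlation between two
#' TFs at a common DEG is `sigma_g^2 / (sigma_g^2 + sigma_e^2)`.  Non-DEG
#' L2FCs are `Normal(0, noise_sd)`.  Adjusted p-values are synthesized
#' directly (`Uniform(0, alpha)` for DEGs, `Uniform(alpha, 1)` otherwise)
#' rather than derived from a fitted DE model, because the pipeline consumes
#' DE tables, not counts.  Base means are 1 + log-normal for expressed genes;
#' `n_unexpressed` extra genes get base mean in (0, 1] and `NA` padj.
#' `na_rate` of the L2FC cells are set missing at random (padj is left
#' intact, mirroring where NA exclusion bites in downstream pairing).
#'
#' @param regime `"independent"`, `"disjoint"` or `"constrained"`.
#' @param n_tfs number of contrasts (default 4).
#' @param universe_size expressed-universe size per TF, scalar or length
#'   `n_tfs` (default 10000).
#' @param deg_count DEGs per TF, scalar or length `n_tfs` (default 1000).
#' @param core_size size of the shared constrained core (default 1500).
#' @param rho fraction of each TF's DEGs drawn from the core, in `[0, 1]`
#'   (default 0.8); used only by the constrained regime.
#' @param sigma_g shared gene-level effect sd (default 1).
#' @param sigma_e TF-specific effect sd (default 0.5).
#' @param noise_sd non-DEG L2FC sd (default 0.2).
#' @param alpha significance threshold the padj model straddles (default
#'   0.05).
#' @param base_mean_meanlog,base_mean_sdlog log-normal parameters of the
#'   expressed base-mean model (defaults log(50), 1.5).
#' @param n_unexpressed genes below the expression threshold added per table
#'   (default 500).
#' @param na_rate fraction of L2FC cells set to `NA` (default 0).
#' @param seed integer seed.
#' @return A validated list of class `regime_config`.
#' @export
regime_config <- function(regime = c("independent", "disjoint", "constrained"),
                          n_tfs = 4, universe_size = 10000, deg_count = 1000,
                          core_size = 1500, rho = 0.8,
                          sigma_g = 1, sigma_e = 0.5, noise_sd = 0.2,
                          alpha = 0.05,
                          base_mean_meanlog = log(50), base_mean_sdlog = 1.5,
                          n_unexpressed = 500, na_rate = 0, seed = 1) {
  regime <- match.arg(regime)
  .assert(n_tfs >= 1, "n_tfs must be >= 1")
  N <- rep_len(universe_size, n_tfs)
  D <- rep_len(deg_count, n_tfs)
  .assert(all(N > 0) && all(D > 0), "universe_size and deg_count must be positive")
  .assert(all(D <= N), "infeasible config: deg_count exceeds universe_size")
  .assert(rho >= 0 && rho <= 1, "rho must lie in [0, 1]")
  .assert(na_rate >= 0 && na_rate < 1, "na_rate must lie in [0, 1)")
  .assert(sigma_g >= 0 && sigma_e >= 0 && noise_sd >= 0,
          "effect sds must be non-negative")
  if (regime == "disjoint") {
    .assert(sum(D) <= min(N),
            "infeasible config: disjoint regime needs sum(deg_count) <= universe_size")
  }
  if (regime == "constrained") {
    .assert(core_size <= min(N),
            "infeasible config: core_size exceeds universe_size")
    .assert(all(round(rho * D) <= core_size),
            "infeasible config: rho * deg_count exceeds core_size")
  }
  structure(list(regime = regime, n_tfs = n_tfs, universe_size = N,
                 deg_count = D, core_size = core_size, rho = rho,
                 sigma_g = sigma_g, sigma_e = sigma_e, noise_sd = noise_sd,
                 alpha = alpha, base_mean_meanlog = base_mean_meanlog,
                 base_mean_sdlog = base_mean_sdlog,
                 n_unexpressed = n_unexpressed, na_rate = na_rate,
                 seed = seed),
            class = "regime_config")
}

#' Generate synthetic DE tables under a regulation regime
#'
#' One [de_table] per TF over a shared gene-id namespace, with the structure
#' described in [regime_config()].  Within each table, `deg_count` genes have
#' `padj < alpha` (so [deg_set()] recovers them exactly when `na_rate` leaves
#' padj untouched, as it always does) and `universe_size` genes have base
#' mean > 1.  Fully reproducible from `config$seed`.
#'
#' @param config a [regime_config()].
#' @return Named list of [de_table]s, labelled `TF1..TFn`.
#' @export
gen_de_tables <- function(config) {
  stopifnot(inherits(config, "regime_config"))
  .with_seed(config$seed, {
    n_tfs <- config$n_tfs
    N <- config$universe_size
    D <- config$deg_count
    n_genes <- max(N) + config$n_unexpressed
    gene_ids <- sprintf("g%06d", seq_len(n_genes))
    # genes 1..max(N) are the expressed pool; each TF's universe is a prefix
    # of it so universes of unequal size are nested, as in real analyses
    # where most expressed genes are common to all contrasts
    g_shared <- stats::rnorm(n_genes, 0, config$sigma_g)

    core <- integer(0)
    if (config$regime == "constrained") {
      core <- sample.int(min(N), config$core_size)
    }
    deg_pool_used <- integer(0)  # for the disjoint regime

    tables <- vector("list", n_tfs)
    for (i in seq_len(n_tfs)) {
      expressed <- seq_len(N[i])
      deg_idx <- switch(config$regime,
        independent = sample(expressed, D[i]),
        disjoint = {
          avail <- setdiff(expressed, deg_pool_used)
          picked <- sample(avail, D[i])
          deg_pool_used <- c(deg_pool_used, picked)
          picked
        },
        constrained = {
          n_core <- round(config$rho * D[i])
          picked <- sample(core, n_core)
          c(picked, sample(setdiff(expressed, picked), D[i] - n_core))
        })
      is_deg <- seq_len(n_genes) %in% deg_idx
      base_mean <- numeric(n_genes)
      base_mean[seq_len(N[i])] <-
        1 + stats::rlnorm(N[i], config$base_mean_meanlog, config$base_mean_sdlog)
      above <- seq_len(n_genes) > N[i]
      base_mean[above] <- stats::runif(sum(above), 0, 1)
      l2fc <- stats::rnorm(n_genes, 0, config$noise_sd)
      l2fc[is_deg] <- g_shared[is_deg] +
        stats::rnorm(sum(is_deg), 0, config$sigma_e)
      padj <- stats::runif(n_genes, config$alpha, 1)
      padj[is_deg] <- stats::runif(sum(is_deg), 0, config$alpha)
      padj[above] <- NA_real_  # filtered out: not expressed in this contrast
      pvalue <- padj * stats::runif(n_genes, 0.2, 1)  # raw p <= BH-adjusted p
      if (config$na_rate > 0) {
        drop <- stats::runif(n_genes) < config$na_rate
        l2fc[drop] <- NA_real_
      }
      tables[[i]] <- de_table(gene_ids, base_mean, l2fc, pvalue, padj,
                              analysis_label = sprintf("TF%d", i))
    }
    names(tables) <- vapply(tables, analysis_label, "")
    tables
  })
}

#' Generate a synthetic count matrix
#'
#' Negative-binomial counts with per-gene log-normal abundance and per-sample
#' library-size multipliers; transcript lengths are log-uniform in
#' `[0.5, 10]` kb.  A fixture generator for the normalization utilities.
#'
#' @param n_genes,n_samples dimensions.
#' @param lib_mult per-sample library-size multipliers; either a scalar
#'   "spread" `s >= 1` (multipliers drawn log-uniform in `[1/s, s]`) or a
#'   vector of length `n_samples`.
#' @param dispersion negative-binomial dispersion (`size = 1/dispersion`);
#'   default 0.1.
#' @param seed integer seed.
#' @return A [count_matrix] with `lengths_kb`.
#' @export
gen_count_matrix <- function(n_genes, n_samples, lib_mult = 1,
                             dispersion = 0.1, seed = 1) {
  .assert(n_genes > 0 && n_samples > 0, "dimensions must be positive")
  .with_seed(seed, {
    mult <- if (length(lib_mult) == 1) {
      .assert(lib_mult >= 1, "scalar lib_mult spread must be >= 1")
      exp(stats::runif(n_samples, -log(lib_mult), log(lib_mult)))
    } else {
      .assert(length(lib_mult) == n_samples,
              "lib_mult must be scalar or length n_samples")
      lib_mult
    }
    mu <- stats::rlnorm(n_genes, log(100), 1)
    counts <- matrix(0, n_genes, n_samples,
                     dimnames = list(sprintf("g%06d", seq_len(n_genes)),
                                     sprintf("s%02d", seq_len(n_samples))))
    for (j in seq_len(n_samples)) {
      counts[, j] <- stats::rnbinom(n_genes, mu = mu * mult[j],
                                    size = 1 / dispersion)
    }
    lengths <- exp(stats::runif(n_genes, log(0.5), log(10)))
    names(lengths) <- rownames(counts)
    count_matrix(counts, lengths_kb = lengths)
  })
}

#' Generate a transgene/endogenous replicate fixture
#'
#' Log-normal replicate counts/kb around stated transgene and endogenous
#' means with a given coefficient of variation, so [expression_ratio()]
#' recovers `uas_mean / endo_mean` up to sampling error (`cv = 0` gives
#' constant replicates and the exact ratio).
#'
#' @param endo_mean,uas_mean true replicate means (counts/kb).
#' @param cv coefficient of variation of the replicates.
#' @param n_reps replicates per group (default 6).
#' @param seed integer seed.
#' @return List with numeric vectors `uas` and `endo`.
#' @export
gen_transgene_fixture <- function(endo_mean, uas_mean, cv = 0.4, n_reps = 6,
                                  seed = 1) {
  .assert(endo_mean > 0 && uas_mean > 0, "means must be positive")
  .assert(cv >= 0, "cv must be non-negative")
  .with_seed(seed, {
    draw <- function(m) {
      if (cv == 0) return(rep(m, n_reps))
      sdlog <- sqrt(log(1 + cv^2))
      stats::rlnorm(n_reps, log(m) - sdlog^2 / 2, sdlog)
    }
    list(uas = draw(uas_mean), endo = draw(endo_mean))
  })
}

#' Exact overlap distribution by exhaustive enumeration
#'
#' Brute-force oracle for [simulate_overlap()]: enumerates every combination
#' of label draws (each analysis choosing `D_i` distinct labels from
#' `{1..N_i}`) and tallies the exact probability mass of the shared-label
#' count.  Only tiny instances are accepted.
#'
#' @inheritParams expected_overlap
#' @param max_states refuse instances with more than this many draw
#'   combinations (default 1e6).
#' @return Data frame with columns `overlap` and `prob` (summing to 1) and
#'   attribute `mean`.
#' @export
enumerate_overlap_oracle <- function(deg_counts, universe_sizes,
                                     max_states = 1e6) {
  .check_overlap_args(deg_counts, universe_sizes)
  n_states <- prod(choose(universe_sizes, deg_counts))
  .assert(n_states <= max_states,
          "instance too large for enumeration: ", format(n_states),
          " draw combinations (limit ", format(max_states), ")")
  draws <- lapply(seq_along(deg_counts), function(i) {
    utils::combn(universe_sizes[i], deg_counts[i], simplify = FALSE)
  })
  grid <- expand.grid(lapply(draws, seq_along))
  overlaps <- vapply(seq_len(nrow(grid)), function(r) {
    sets <- lapply(seq_along(draws), function(i) draws[[i]][[grid[r, i]]])
    length(Reduce(intersect, sets))
  }, 0L)
  tab <- table(overlaps)
  out <- data.frame(overlap = as.integer(names(tab)),
                    prob = as.numeric(tab) / length(overlaps))
  attr(out, "mean") <- sum(out$overlap * out$prob)
  out
}
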