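# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round to two significant figures
#'
#' Convenience wrapper used when reporting transgene expression ratios the way
#' they appear in summary tables (two significant figures, round-half-even as
#' implemented by [signif()]).
#'
#' @param x numeric vector.
#' @return `x` rounded to two significant figures.
#' @export
signif2 <- function(x) signif(x, 2)

# Deterministic 31-bit hash of a character scalar, used to derive per-subset
# sub-seeds so that adding comparisons to a report never perturbs the others.
.hash_string <- function(s) {
  codes <- utf8ToInt(s)
  h <- 0
  for (cc in codes) h <- (h * 31 + cc) %% 2147483647
  h
}

# Combine a run seed with a comparison label into a reproducible sub-seed.
.subset_seed <- function(seed, labels) {
  key <- paste(sort(labels), collapse = "\x1f")
  as.integer((as.numeric(seed) %% 2147483647 + .hash_string(key)) %% 2147483647)
}

# Evaluate `expr` under a locally seeded RNG, restoring the caller's RNG
# state afterwards so library calls never disturb user-level randomness.
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_state <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_state) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_state) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

.assert <- function(ok, ...) if (!isTRUE(ok)) stop(..., call. = FALSE)
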