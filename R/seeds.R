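## Counter-based seed derivation.  Every stochastic routine in the package
## accepts an integer seed; nested routines derive child seeds from it with
## derive_seed() so that results do not depend on evaluation order or on how
## work is split across replicates.

#' Derive a child seed from a root seed and a key path
#'
#' Produces a deterministic 31-bit seed from a root seed plus any number of
#' integer keys (population index, sample index, method index, replicate
#' index, ...).  The derivation is a multiplicative-congruential fold, so
#' streams for different key paths are distinct by construction and the
#' result never exceeds `.Machine$integer.max`.
#'
#' @param root integer root seed.
#' @param ... integer keys identifying the stream (indices, counters).
#' @return A single integer in `[1, 2^31 - 2]` suitable for [set.seed()].
#' @examples
#' derive_seed(1, 3, 7)
#' derive_seed(1, 3, 8) # different stream
#' @export
derive_seed <- function(root, ...) {
  m <- 2147483647 # 2^31 - 1 (prime)
  a <- 48271      # Lehmer multiplier
  keys <- c(root, ...)
  stopifnot(all(is.finite(keys)))
  x <- 11
  for (k in keys) {
    x <- (a * x + (as.numeric(k) %% m) * 7919 + 1) %% m
    x <- (a * x) %% m
  }
  as.integer(x %% (m - 2) + 1)
}

## Set the RNG locally when a seed is supplied; NULL leaves the global
## stream untouched (interactive use).
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}
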