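## Desk-scale reproduction wrappers for the two simulation benchmarks.
## These drive run_study() with the published study conditions (group
## means, variances, POPtype lists, alpha = 0.05, target power 0.8, 100
## Monte-Carlo samples per candidate size, scan step 5) and reduce only
## the number of repetitions per population, so a laptop run reproduces
## the pooled medians of the full cluster-scale study.

#' Reproduce the pooled run_three medians at desk scale
#'
#' Builds the six run_three populations (group means 100/99/98, variance
#' 20, POPtypes Ba Bb B3a B3b BaN BbN, 10000 values per group), chooses
#' `initialsizeN` by the one-third-of-90%-power rule, and runs the
#' measured Kruskal-Wallis search plus the KRTDIV, ANT and analytical
#' predictions on selected pilot samples.
#'
#' @param seed root integer seed.
#' @param samples_per_population pilot samples per POPtype (default 8;
#'   per-pilot estimates are heavily skewed, so the pooled median
#'   stabilizes visibly with each extra pilot).
#' @param measure_reps measured-search repetitions per population
#'   (default 5).
#' @param n_per_group population group size (default 10000).
#' @param reps Monte-Carlo samples per candidate size (default 100).
#' @param verbose print progress.
#' @return List with the `datastore` and `medians`, the pooled
#'   all-available medians named KRM, KRTDIV, ANT, ANALYTICAL.
#' @export
reproduce_run_three <- function(seed = 1, samples_per_population = 8,
                                measure_reps = 5, n_per_group = 10000,
                                reps = 100, verbose = FALSE) {
  cfg <- kw_run_config("run_three",
                       samples_per_population = samples_per_population,
                       measure_reps = measure_reps,
                       n_per_group = n_per_group, reps = reps,
                       methods = c("KRM", "KRTDIV", "ANT", "ANALYTICAL"))
  ds <- run_study(cfg, seed = seed, verbose = verbose)
  list(datastore = ds, medians = pooled_medians(ds))
}

#' Reproduce the pooled run_one_relaxed medians at desk scale
#'
#' Builds the fifteen run_one_relaxed populations (group means
#' 100/99.5/99, variance 5) and runs relaxed pilot selection
#' (Kruskal-Wallis non-significance only) with the measured and KRTDIV
#' searches.
#'
#' @inheritParams reproduce_run_three
#' @export
reproduce_run_one_relaxed <- function(seed = 1, samples_per_population = 3,
                                      measure_reps = 2, n_per_group = 10000,
                                      reps = 100, verbose = FALSE) {
  cfg <- kw_run_config("run_one_relaxed",
                       samples_per_population = samples_per_population,
                       measure_reps = measure_reps,
                       n_per_group = n_per_group, reps = reps,
                       methods = c("KRM", "KRTDIV"))
  ds <- run_study(cfg, seed = seed, verbose = verbose)
  list(datastore = ds, medians = pooled_medians(ds))
}

#' Pooled all-available medians per method from a datastore
#'
#' @param ds datastore data.frame from [run_study()].
#' @return Named numeric vector of medians of `n_at_power` per method.
#' @export
pooled_medians <- function(ds) {
  vapply(split(ds$n_at_power, ds$method),
         function(v) median(v, na.rm = TRUE), 0)
}
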