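## Monte-Carlo power estimation and sample-size search.  A "group
## generator" is the source contract shared by all method codes: given a
## total sample size and a seed it yields k group samples whose sizes are
## the rounded group proportions of the total (rounding residue assigned to
## the largest group).

#' Split a total sample size into group sizes
#'
#' @param n total sample size.
#' @param proportions per-group fractions summing to 1.
#' @return Integer group sizes summing to `n`.
#' @export
group_sizes <- function(n, proportions) {
  stopifnot(abs(sum(proportions) - 1) < 1e-8)
  sz <- round(proportions * n)
  sz[which.max(proportions)] <- sz[which.max(proportions)] + (n - sum(sz))
  as.integer(sz)
}

#' Construct a power/sample-size query
#'
#' Bundles the Monte-Carlo search settings shared by all method codes.
#'
#' @param test `"KW"` (Kruskal-Wallis) or `"ANOVA_White"`.
#' @param alpha significance level of the individual tests.
#' @param target_power required power (typically 0.8 or 0.9).
#' @param reps Monte-Carlo samples per candidate size (default 100).
#' @param n_start first candidate total size (typically initialsizeN + 1).
#' @param step scan increment (default 5).
#' @param proportions per-group fractions (default equal across 3 groups).
#' @param max_n scan cap (default `20 * n_start`).
#' @return A `kw_power_query` list.
#' @export
power_query <- function(test = c("KW", "ANOVA_White"), alpha = 0.05,
                        target_power = 0.8, reps = 100, n_start = 31,
                        step = 5, proportions = rep(1 / 3, 3),
                        max_n = 20 * n_start) {
  test <- match.arg(test)
  stopifnot(alpha > 0, alpha < 1, target_power > 0, target_power < 1,
            reps >= 1, step >= 1, n_start >= 2 * length(proportions))
  structure(list(test = test, alpha = alpha, target_power = target_power,
                 reps = reps, n_start = n_start, step = step,
                 proportions = proportions, max_n = max_n),
            class = "kw_power_query")
}

test_pvalue <- function(test, groups) {
  if (test == "KW") .kw_p(groups)[2] else .aw_p(groups)[2]
}

## ---- generators -----------------------------------------------------------

#' Group generators for the power engine
#'
#' A generator is a function `(n, seed) -> list of k numeric vectors` with
#' group sizes given by [group_sizes()].  Three backends cover the method
#' codes: finite-population resampling (without replacement within a
#' replicate, a fresh draw per replicate), fitted Bernstein models
#' (duplication = one fit per group; division = equal-weight mixture of the
#' two half fits), and per-group normal fits.
#'
#' @param pop a `kw_population`.
#' @return A generator function.
#' @export
generator_population <- function(pop) {
  groups <- pop$groups
  props <- pop$proportions
  function(n, seed = NULL) {
    sz <- group_sizes(n, props)
    with_seed(seed,
      Map(function(g, k) g[sample.int(length(g), k)], groups, as.list(sz)))
  }
}

#' @rdname generator_population
#' @param models a `kw_group_models` from [fit_groups()].
#' @export
generator_bernstein <- function(models) {
  fits <- models$fits
  props <- models$proportions
  function(n, seed = NULL) {
    sz <- group_sizes(n, props)
    with_seed(seed,
      Map(function(f, k) {
        if (length(f) == 1) {
          as.numeric(simulate_model(f[[1]], k))
        } else {
          take <- stats::rbinom(1, k, 0.5)
          as.numeric(c(simulate_model(f[[1]], take),
                       simulate_model(f[[2]], k - take)))
        }
      }, fits, as.list(sz)))
  }
}

#' @rdname generator_population
#' @param means,sds per-group normal parameters.
#' @param proportions per-group fractions.
#' @export
generator_normal <- function(means, sds, proportions = NULL) {
  if (is.null(proportions)) proportions <- rep(1 / length(means), length(means))
  function(n, seed = NULL) {
    sz <- group_sizes(n, proportions)
    with_seed(seed,
      Map(function(m, s, k) rnorm(k, m, s), means, sds, as.list(sz)))
  }
}

## ---- power estimation and search -----------------------------------------

#' Monte-Carlo power at a fixed sample size
#'
#' Fraction of `q$reps` generated samples whose test p-value falls below
#' `q$alpha`, with its binomial standard error.  Replicates are seeded
#' individually from `seed` so the estimate is independent of evaluation
#' order.
#'
#' @param gen group generator (see [generator_population()]).
#' @param n total sample size.
#' @param q a `kw_power_query`.
#' @param seed integer seed.
#' @return List with `power`, `se`, `n`, `reps`.
#' @export
estimate_power <- function(gen, n, q, seed = NULL) {
  stopifnot(n >= 2 * length(q$proportions))
  hits <- vapply(seq_len(q$reps), function(i) {
    s <- gen(n, derive_seed(seed %||% 0, n, i))
    test_pvalue(q$test, s) < q$alpha
  }, TRUE)
  p <- mean(hits)
  list(power = p, se = sqrt(p * (1 - p) / q$reps), n = n, reps = q$reps)
}

## regenerate the significant replicates at the crossing and return the
## median of their minimum folded pairwise effect sizes
crossing_min_effect <- function(gen, n, q, seed) {
  eff <- vapply(seq_len(q$reps), function(i) {
    s <- gen(n, derive_seed(seed %||% 0, n, i))
    if (test_pvalue(q$test, s) < q$alpha) min_effect_size(s) else NA_real_
  }, 0)
  median(eff, na.rm = TRUE)
}

#' Search the sample size reaching target power
#'
#' Scans total sizes `n_start, n_start + step, ...` up to `max_n` and
#' returns the first size whose Monte-Carlo power estimate reaches the
#' target.  Failure to reach the target within the scan is recorded as a
#' value (`failed = TRUE`, `n_at_power = NA`), matching the missing-data
#' semantics of the study runner.
#'
#' @param gen group generator.
#' @param q a `kw_power_query`.
#' @param seed integer seed.
#' @param method_code label stored on the estimate (method bookkeeping).
#' @return An object of class `kw_sample_size`: `method_code`,
#'   `n_at_power` (or NA), `power_at_n`, `min_effect` (median over
#'   significant replicates at the crossing), `failed`, and `curve`
#'   (data.frame of n and estimated power).
#' @export
find_sample_size <- function(gen, q, seed = NULL, method_code = NA_character_) {
  ns <- seq(q$n_start, q$max_n, by = q$step)
  curve_n <- integer(0); curve_p <- numeric(0)
  hit <- NA_integer_; hit_p <- NA_real_
  for (n in ns) {
    est <- estimate_power(gen, n, q, seed = seed)
    curve_n <- c(curve_n, n); curve_p <- c(curve_p, est$power)
    if (est$power >= q$target_power) { hit <- n; hit_p <- est$power; break }
  }
  min_eff <- if (!is.na(hit)) crossing_min_effect(gen, hit, q, seed) else NA_real_
  structure(list(method_code = method_code,
                 n_at_power = hit, power_at_n = hit_p, min_effect = min_eff,
                 failed = is.na(hit),
                 curve = data.frame(n = curve_n, power = curve_p),
                 query = q),
            class = "kw_sample_size")
}

#' @export
print.kw_sample_size <- function(x, ...) {
  if (x$failed) {
    cat("Sample-size search (", x$method_code, "): target power not reached ",
        "within scan (max n = ", max(x$curve$n), ")\n", sep = "")
  } else {
    cat("Sample-size search (", x$method_code, "): n = ", x$n_at_power,
        " at power ", format(x$power_at_n, digits = 3),
        " (min effect ", format(x$min_effect, digits = 3), ")\n", sep = "")
  }
  invisible(x)
}

## ---- method codes ---------------------------------------------------------

#' Predicted sample size from Bernstein fits (KRTDUP / KRTDIV)
#'
#' Fits monotone Bernstein transformation models to each pilot group
#' (duplication or division preprocessing), then searches the Kruskal-Wallis
#' Monte-Carlo power curve of samples simulated from the fits.
#'
#' @param sample list of pilot group vectors.
#' @param mode `"div"` or `"dup"`.
#' @param q a `kw_power_query` (test forced to `"KW"`).
#' @param seed integer seed.
#' @param order Bernstein order (default 4).
#' @return A `kw_sample_size` (failed if any group fit fails).
#' @export
predicted_kw <- function(sample, mode = c("div", "dup"), q, seed = NULL,
                         order = 4) {
  mode <- match.arg(mode)
  q$test <- "KW"
  code <- if (mode == "div") "KRTDIV" else "KRTDUP"
  models <- tryCatch(
    fit_groups(sample, mode = mode, order = order,
               seed = derive_seed(seed %||% 0, 1)),
    error = function(e) NULL)
  if (is.null(models)) {
    return(structure(list(method_code = code, n_at_power = NA_integer_,
                          power_at_n = NA_real_, min_effect = NA_real_,
                          failed = TRUE,
                          curve = data.frame(n = integer(0), power = numeric(0)),
                          query = q),
                     class = "kw_sample_size"))
  }
  find_sample_size(generator_bernstein(models), q,
                   seed = derive_seed(seed %||% 0, 2), method_code = code)
}

#' Predicted sample size from per-group normal fits (ANT)
#'
#' Fits a normal distribution to each pilot group and searches the
#' Monte-Carlo power curve of the White-adjusted one-way ANOVA.
#'
#' @inheritParams predicted_kw
#' @return A `kw_sample_size`.
#' @export
predicted_anova <- function(sample, q, seed = NULL) {
  stopifnot(all(lengths(sample) >= 2))
  q$test <- "ANOVA_White"
  gen <- generator_normal(vapply(sample, mean, 0), vapply(sample, sd, 0),
                          lengths(sample) / sum(lengths(sample)))
  find_sample_size(gen, q, seed = derive_seed(seed %||% 0, 3),
                   method_code = "ANT")
}

#' Measured sample size by population resampling (KRM / ANM)
#'
#' Resamples the finite population at increasing total sizes (without
#' replacement within a replicate, fresh draw each replicate) and searches
#' the Monte-Carlo power curve.
#'
#' @param pop a `kw_population`.
#' @param q a `kw_power_query` (`test` selects KRM vs ANM).
#' @param seed integer seed.
#' @return A `kw_sample_size`.
#' @export
measured_sample_size <- function(pop, q, seed = NULL) {
  pop_n <- min(lengths(pop$groups) / pop$proportions)
  if (q$max_n > pop_n) q$max_n <- pop_n
  code <- if (q$test == "KW") "KRM" else "ANM"
  find_sample_size(generator_population(pop), q, seed = seed,
                   method_code = code)
}

#' Analytical noncentral-F ANOVA sample size
#'
#' Computes the balanced one-way ANOVA power
#' \eqn{P(F' > F_{crit}(\alpha; k-1, k(n-1)); \lambda(n))} with
#' noncentrality \eqn{\lambda(n) = (k-1)\,n\,V_{means}/\sigma^2_w
#' = n \sum_j (\mu_j - \bar\mu)^2 / \sigma^2_w}, where \eqn{V_{means}} is
#' the (k-1)-divisor variance of the group means, and
#' returns the smallest per-group `n` reaching the target power by
#' monotone search (integer grid plus continuous refinement).
#'
#' @param group_means group means (not all equal).
#' @param within_var common within-group variance (> 0).
#' @param alpha significance level.
#' @param target_power required power.
#' @param proportions optional per-group fractions used to convert the
#'   balanced per-group size into a total (default equal).
#' @return List with `n_per_group` (continuous), `total`
#'   (`ceiling(k * n_per_group)` at equal allocation), and `power` at the
#'   returned size.
#' @export
analytical_anova_n <- function(group_means, within_var, alpha = 0.05,
                               target_power = 0.8, proportions = NULL) {
  k <- length(group_means)
  stopifnot(k >= 2, within_var > 0)
  vm <- var(group_means)
  if (vm == 0) stop("all group means equal: no finite sample size")
  pow <- function(n) { # n per group, n > 1
    df2 <- k * (n - 1)
    lambda <- (k - 1) * n * vm / within_var
    pf(qf(1 - alpha, k - 1, df2), k - 1, df2, ncp = lambda,
       lower.tail = FALSE)
  }
  ## monotone search: double until power reached, then continuous refine
  n_hi <- 2
  while (pow(n_hi) < target_power) {
    n_hi <- n_hi * 2
    if (n_hi > 1e7) stop("required sample size beyond search bound")
  }
  n_lo <- max(n_hi / 2, 1 + 1e-9)
  n <- if (pow(n_lo) >= target_power && n_lo <= 2) {
    n_lo
  } else {
    uniroot(function(n) pow(n) - target_power, c(n_lo, n_hi),
            tol = 1e-8)$root
  }
  total <- ceiling(k * n)
  if (!is.null(proportions)) {
    ## balanced solution rescaled: total such that the smallest group still
    ## reaches n
    total <- ceiling(n / min(proportions))
  }
  list(n_per_group = n, total = total, power = pow(n))
}
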