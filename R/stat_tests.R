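## Hypothesis tests and effect sizes used throughout the package.  The
## power engine calls the internal .p() variants, which skip object
## construction in tight Monte-Carlo loops.

kw_test_result <- function(statistic, df, p_value, method) {
  structure(list(statistic = statistic, df = df, p_value = p_value,
                 method = method),
            class = "kw_test_result")
}

#' @export
print.kw_test_result <- function(x, ...) {
  cat(x$method, "\n  statistic = ", format(x$statistic, digits = 5),
      ", df = ", paste(x$df, collapse = ", "),
      ", p = ", format(x$p_value, digits = 4), "\n", sep = "")
  invisible(x)
}

## Kruskal-Wallis p-value, mid-ranks and tie correction.
.kw_p <- function(groups) {
  x <- unlist(groups, use.names = FALSE)
  N <- length(x)
  r <- rank(x)
  g <- rep.int(seq_along(groups), lengths(groups))
  Rsum <- vapply(split(r, g), sum, 0)
  n <- lengths(groups)
  H <- 12 / (N * (N + 1)) * sum(Rsum^2 / n) - 3 * (N + 1)
  tt <- rle(sort(x))$lengths
  C <- 1 - sum(tt^3 - tt) / (N^3 - N)
  if (C <= 0) return(c(NaN, NaN))
  H <- H / C
  c(H, pchisq(H, length(groups) - 1, lower.tail = FALSE))
}

#' Kruskal-Wallis rank test with tie correction
#'
#' Computes \eqn{H = [12/(N(N+1)) \sum_i R_i^2/n_i - 3(N+1)] /
#' [1 - \sum(t^3 - t)/(N^3 - N)]} with mid-ranks, and refers it to a
#' chi-squared distribution with k - 1 degrees of freedom.
#'
#' @param groups list of numeric vectors (>= 2 groups, each non-empty).
#' @return A `kw_test_result` with fields `statistic` (H), `df`, `p_value`.
#' @examples
#' kruskal_wallis(list(1:3, 4:6, 7:9)) # H = 7.2
#' @export
kruskal_wallis <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2, all(lengths(groups) >= 1))
  x <- unlist(groups, use.names = FALSE)
  if (length(unique(x)) == 1) {
    stop("all values identical: Kruskal-Wallis statistic undefined")
  }
  hp <- .kw_p(groups)
  kw_test_result(hp[1], length(groups) - 1, hp[2],
                 "Kruskal-Wallis rank sum test (tie-corrected)")
}

## One-way heteroskedasticity-consistent Wald test of equal group means.
## With group-indicator regressors the HC covariance is diagonal in the
## group means, so the Wald statistic reduces to the weighted dispersion
## sum_j w_j (m_j - m_w)^2 with w_j the inverse HC variance of mean j.
.aw_p <- function(groups, hc = "HC3") {
  k <- length(groups)
  n <- lengths(groups)
  N <- sum(n)
  mns <- vapply(groups, mean, 0)
  ss <- mapply(function(g, m) sum((g - m)^2), groups, mns)
  v <- switch(hc,
    HC0 = ss / n^2,
    HC1 = (N / (N - k)) * ss / n^2,
    HC3 = ss / ((1 - 1 / n)^2) / n^2)
  if (any(v == 0)) v[v == 0] <- .Machine$double.xmin
  w <- 1 / v
  mw <- sum(w * mns) / sum(w)
  W <- sum(w * (mns - mw)^2)
  Fstat <- W / (k - 1)
  c(Fstat, pf(Fstat, k - 1, N - k, lower.tail = FALSE))
}

#' White-adjusted one-way ANOVA (heteroskedasticity-consistent Wald test)
#'
#' Tests equality of group means in the one-way mean model with a
#' heteroskedasticity-consistent covariance estimate (default HC3), with an
#' F reference on (k - 1, N - k) degrees of freedom.  A group with only two
#' observations and zero variance makes the HC3 leverage correction
#' degenerate; in that case the test falls back to HC1 with a warning.
#'
#' @param groups list of numeric vectors (>= 2 groups, each with >= 2
#'   values).
#' @param hc_variant `"HC3"` (default), `"HC1"` or `"HC0"`.
#' @return A `kw_test_result` with the Wald F statistic, numerator and
#'   denominator df, and p-value.
#' @export
anova_white <- function(groups, hc_variant = c("HC3", "HC1", "HC0")) {
  hc_variant <- match.arg(hc_variant)
  stopifnot(is.list(groups), length(groups) >= 2, all(lengths(groups) >= 2))
  if (hc_variant == "HC3") {
    degen <- vapply(groups, function(g) length(g) == 2 && var(g) == 0, TRUE)
    if (any(degen)) {
      warning("zero-variance group of size 2 under HC3; falling back to HC1")
      hc_variant <- "HC1"
    }
  }
  fp <- .aw_p(groups, hc_variant)
  k <- length(groups)
  kw_test_result(fp[1], c(k - 1, sum(lengths(groups)) - k), fp[2],
                 paste0("White-adjusted one-way ANOVA (", hc_variant, ")"))
}

#' Brown-Mood median test
#'
#' Dichotomizes all values at the pooled grand median (strictly greater
#' counts as "above"; ties at the median count "below") and tests the
#' resulting 2 x k table by chi-squared with k - 1 df.  Pairwise
#' comparisons recompute the grand median for each pair and report a signed
#' two-proportion Z with Bonferroni-adjusted p-values.
#'
#' @param groups list of numeric vectors (>= 2 groups).
#' @param pairwise logical; also compute pairwise comparisons.
#' @return A `kw_test_result`; when `pairwise = TRUE` it carries a
#'   `pairwise` data.frame (columns `g1`, `g2`, `Z`, `p_raw`, `p_adj`).
#' @export
brown_mood_median <- function(groups, pairwise = TRUE) {
  stopifnot(is.list(groups), length(groups) >= 2, all(lengths(groups) >= 1))
  k <- length(groups)
  n <- lengths(groups)
  gm <- median(unlist(groups, use.names = FALSE))
  above <- vapply(groups, function(g) sum(g > gm), 0)
  A <- sum(above); N <- sum(n)
  if (A == 0 || A == N) {
    res <- kw_test_result(0, k - 1, 1, "Brown-Mood median test")
  } else {
    e_above <- n * A / N
    e_below <- n * (N - A) / N
    stat <- sum((above - e_above)^2 / e_above +
                ((n - above) - e_below)^2 / e_below)
    res <- kw_test_result(stat, k - 1,
                          pchisq(stat, k - 1, lower.tail = FALSE),
                          "Brown-Mood median test")
  }
  if (pairwise) {
    pr <- t(utils::combn(k, 2))
    m <- nrow(pr)
    Z <- praw <- numeric(m)
    for (i in seq_len(m)) {
      g1 <- groups[[pr[i, 1]]]; g2 <- groups[[pr[i, 2]]]
      gm2 <- median(c(g1, g2))
      a1 <- sum(g1 > gm2); a2 <- sum(g2 > gm2)
      ph <- (a1 + a2) / (length(g1) + length(g2))
      se <- sqrt(ph * (1 - ph) * (1 / length(g1) + 1 / length(g2)))
      Z[i] <- if (se == 0) 0 else (a1 / length(g1) - a2 / length(g2)) / se
      praw[i] <- 2 * pnorm(-abs(Z[i]))
    }
    res$pairwise <- data.frame(g1 = pr[, 1], g2 = pr[, 2], Z = Z,
                               p_raw = praw, p_adj = pmin(1, m * praw))
  }
  res
}

#' Vargha and Delaney's A effect size
#'
#' Probability of superiority \eqn{A = [\#(x_i > y_j) + 0.5\,\#(x_i = y_j)]
#' / (n_x n_y)}, computed via rank sums in O(n log n).  0.5 means
#' stochastic equality.
#'
#' @param x,y numeric vectors (non-empty).
#' @return A probability in `[0, 1]`.
#' @examples
#' vargha_delaney_A(c(1, 2), c(1, 3)) # 0.375
#' @export
vargha_delaney_A <- function(x, y) {
  stopifnot(length(x) >= 1, length(y) >= 1)
  nx <- length(x); ny <- length(y)
  r <- rank(c(x, y))
  (sum(r[seq_len(nx)]) - nx * (nx + 1) / 2) / (nx * ny)
}

#' Minimum folded pairwise effect size
#'
#' For every pair of groups computes the folded Vargha-Delaney effect
#' \eqn{A^* = \max(A, 1 - A)} and returns the extreme over pairs: the
#' minimum (default) is the smallest pairwise separation present when a
#' global test reaches significance.
#'
#' @param groups list of numeric vectors (>= 2 groups).
#' @param fold `"min"` (default) or `"max"` over pairs.
#' @return A probability >= 0.5.
#' @export
min_effect_size <- function(groups, fold = c("min", "max")) {
  fold <- match.arg(fold)
  stopifnot(is.list(groups), length(groups) >= 2)
  pr <- utils::combn(length(groups), 2)
  As <- apply(pr, 2, function(ij) {
    a <- vargha_delaney_A(groups[[ij[1]]], groups[[ij[2]]])
    max(a, 1 - a)
  })
  if (fold == "min") min(As) else max(As)
}

#' Median and raw median absolute deviation
#'
#' The MAD here uses constant 1 (no 1.4826 normal-consistency scaling), the
#' convention used for all robust summaries in the package.
#'
#' @param values numeric vector (non-empty), NAs dropped.
#' @return Named numeric `c(median, mad)`.
#' @examples
#' median_mad(1:5) # 3, 1
#' @export
median_mad <- function(values) {
  values <- values[!is.na(values)]
  stopifnot(length(values) >= 1)
  c(median = median(values), mad = mad(values, constant = 1))
}
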