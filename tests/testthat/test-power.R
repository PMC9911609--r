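test_that("group sizes follow rounded proportions with residue to largest", {
  expect_equal(group_sizes(10, c(1 / 3, 1 / 3, 1 / 3)), c(4L, 3L, 3L))
  expect_equal(sum(group_sizes(101, c(0.5, 0.3, 0.2))), 101L)
  expect_equal(group_sizes(100, c(0.5, 0.3, 0.2)), c(50L, 30L, 20L))
  expect_equal(group_sizes(7, c(0.6, 0.4)), c(4L, 3L))
})

test_that("estimate_power is calibrated at the null (type-I error)", {
  gen <- generator_normal(c(0, 0, 0), c(1, 1, 1))
  q <- power_query(test = "KW", alpha = 0.05, reps = 2000, n_start = 90)
  est <- estimate_power(gen, 90, q, seed = 1)
  expect_gt(est$power, 0.035)
  expect_lt(est$power, 0.065)
})

test_that("estimate_power saturates for disjoint supports", {
  gen <- function(n, seed = NULL) {
    sz <- group_sizes(n, rep(1 / 3, 3))
    kwpower:::with_seed(seed, list(runif(sz[1], 0, 1), runif(sz[2], 5, 6),
                                   runif(sz[3], 10, 11)))
  }
  q <- power_query(test = "KW", reps = 50, n_start = 9)
  expect_equal(estimate_power(gen, 9, q, seed = 2)$power, 1)
})

test_that("Monte-Carlo ANOVA power matches the noncentral-F closed form", {
  means <- c(0, 0.4, 0.8); sds <- c(1, 1, 1)
  gen <- generator_normal(means, sds)
  q <- power_query(test = "ANOVA_White", alpha = 0.05, reps = 1000,
                   n_start = 60)
  est <- estimate_power(gen, 60, q, seed = 3)
  exact <- power.anova.test(groups = 3, n = 20, between.var = var(means),
                            within.var = 1)$power
  expect_lt(abs(est$power - exact), 3 * sqrt(exact * (1 - exact) / 1000) + 0.02)
})

test_that("find_sample_size returns grid sizes and records the curve", {
  gen <- generator_normal(c(0, 3, 6), c(0.5, 0.5, 0.5))
  q <- power_query(test = "KW", reps = 40, n_start = 12, step = 5,
                   max_n = 200)
  est <- find_sample_size(gen, q, seed = 4)
  expect_false(est$failed)
  expect_equal(est$n_at_power, 12)        # power 1 already at n_start
  expect_equal(est$curve$n[1], 12)
  # null generator fails within the scan cap
  gen0 <- generator_normal(c(0, 0, 0), c(1, 1, 1))
  q0 <- power_query(test = "KW", reps = 30, n_start = 12, step = 5,
                    max_n = 42)
  est0 <- find_sample_size(gen0, q0, seed = 5)
  expect_true(est0$failed)
  expect_true(is.na(est0$n_at_power))
  expect_equal(est0$curve$n, seq(12, 42, 5))
  # any crossing obeys n == n_start (mod step)
  gen2 <- generator_normal(c(0, 0.8, 1.6), c(1, 1, 1))
  q2 <- power_query(test = "KW", reps = 60, n_start = 13, step = 5,
                    max_n = 500)
  est2 <- find_sample_size(gen2, q2, seed = 6)
  expect_false(est2$failed)
  expect_equal((est2$n_at_power - 13) %% 5, 0)
  expect_gte(est2$power_at_n, 0.8)
  expect_gte(est2$min_effect, 0.5)
})

test_that("estimated power is monotone in n up to binomial noise", {
  gen <- generator_normal(c(0, 0.5, 1), c(1, 1, 1))
  q <- power_query(test = "KW", reps = 400, n_start = 12)
  ns <- seq(12, 92, by = 10)
  pw <- vapply(ns, function(n) estimate_power(gen, n, q, seed = 7)$power, 0)
  iso <- isoreg(ns, pw)
  se <- sqrt(mean(pw * (1 - pw)) / 400)
  expect_lt(max(abs(iso$yf - pw)), 3 * se)
})

test_that("predicted searches are deterministic in the seed", {
  set.seed(8)
  s <- lapply(c(0, 1, 2), function(m) rnorm(30, m, 1))
  q <- power_query(reps = 40, n_start = 31, step = 5, max_n = 400)
  a <- predicted_kw(s, "div", q, seed = 11)
  b <- predicted_kw(s, "div", q, seed = 11)
  expect_identical(a$n_at_power, b$n_at_power)
  expect_identical(a$curve, b$curve)
  c2 <- predicted_anova(s, q, seed = 12)
  d <- predicted_anova(s, q, seed = 12)
  expect_identical(c2$n_at_power, d$n_at_power)
})

test_that("duplication and division give similar predictions", {
  set.seed(9)
  s <- lapply(c(0, 0.7, 1.4), function(m) rnorm(40, m, 1))
  q <- power_query(reps = 60, n_start = 31, step = 5, max_n = 600)
  dup <- vapply(1:8, function(i) predicted_kw(s, "dup", q, seed = i)$n_at_power, 0)
  div <- vapply(1:8, function(i) predicted_kw(s, "div", q, seed = 100 + i)$n_at_power, 0)
  expect_lte(abs(median(dup) - median(div)), 2 * q$step)
})

test_that("predicted_anova on normal pilots tracks the analytical size", {
  set.seed(10)
  s <- lapply(c(0, 0.5, 1), function(m) {
    x <- rnorm(300); m + (x - mean(x)) / sd(x)
  })
  an <- analytical_anova_n(vapply(s, mean, 0), mean(vapply(s, var, 0)),
                           alpha = 0.05, target_power = 0.8)
  q <- power_query(test = "ANOVA_White", reps = 400, n_start = 16, step = 5,
                   max_n = 400)
  est <- predicted_anova(s, q, seed = 13)
  expect_false(est$failed)
  expect_lte(abs(est$n_at_power - an$total), 2 * q$step)
})

test_that("zero-variance distinct-mean pilots cross immediately", {
  s <- list(rep(1, 5), rep(2, 5), rep(3, 5))
  q <- power_query(test = "ANOVA_White", reps = 20, n_start = 9, step = 5,
                   max_n = 50)
  expect_equal(predicted_anova(s, q, seed = 14)$n_at_power, 9)
})

test_that("measured search on disjoint-support population returns n_start", {
  pop <- fast_population(gap = 20)
  q <- power_query(test = "KW", reps = 30, n_start = 9, step = 5,
                   max_n = 200)
  est <- measured_sample_size(pop, q, seed = 15)
  expect_equal(est$n_at_power, 9)
  expect_equal(est$method_code, "KRM")
})

test_that("analytical sample size matches power.anova.test and is monotone", {
  an <- analytical_anova_n(c(100, 99, 98), 20, alpha = 0.05,
                           target_power = 0.8)
  ref <- power.anova.test(groups = 3, between.var = var(c(100, 99, 98)),
                          within.var = 20, power = 0.8)$n
  expect_equal(an$n_per_group, ref, tolerance = 1e-6)
  expect_equal(an$total, ceiling(3 * ref))
  expect_error(analytical_anova_n(c(1, 1, 1), 2), "equal")
  # power strictly increasing in n
  pws <- vapply(c(20, 40, 80, 160), function(n) {
    df2 <- 3 * (n - 1)
    pf(qf(0.95, 2, df2), 2, df2, ncp = 2 * n * 0.09 / 1, lower.tail = FALSE)
  }, 0)
  expect_true(all(diff(pws) > 0))
})

test_that("two-group KW power matches Wilcoxon rank-sum power", {
  gen <- generator_normal(c(0, 0.6), c(1, 1), c(0.5, 0.5))
  q <- power_query(test = "KW", alpha = 0.05, reps = 600, n_start = 40)
  pk <- estimate_power(gen, 40, q, seed = 31)$power
  pw <- kwpower:::with_seed(32, mean(replicate(600, {
    g <- gen(40)
    wilcox.test(g[[1]], g[[2]], exact = FALSE, correct = FALSE)$p.value < 0.05
  })))
  expect_lt(abs(pk - pw), 3 * sqrt(pk * (1 - pk) / 600) + 0.02)
})

test_that("find_sample_size reuses per-replicate streams reproducibly", {
  pop <- fast_population(gap = 0.8)
  q <- power_query(test = "KW", reps = 50, n_start = 21, step = 5,
                   max_n = 300)
  e1 <- measured_sample_size(pop, q, seed = 77)
  e2 <- measured_sample_size(pop, q, seed = 77)
  expect_identical(e1$curve, e2$curve)
  expect_identical(e1$min_effect, e2$min_effect)
})
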