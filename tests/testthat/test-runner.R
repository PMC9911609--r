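test_that("built-in run configurations carry the published settings", {
  r3 <- kw_run_config("run_three")
  expect_equal(r3$group_means, c(100, 99, 98))
  expect_equal(r3$variance, 20)
  expect_setequal(r3$poptypes, c("Ba", "Bb", "B3a", "B3b", "BaN", "BbN"))
  r1r <- kw_run_config("run_one_relaxed")
  expect_equal(r1r$group_means, c(100, 99.5, 99))
  expect_equal(r1r$variance, 5)
  expect_length(r1r$poptypes, 15)
  expect_true(r1r$relaxed)
  r2 <- kw_run_config("run_two", samples_per_population = 4)
  expect_equal(r2$group_means, c(100, 99.7, 99.45))
  expect_equal(r2$samples_per_population, 4)
})

test_that("initial size rule: one third of the 90% crossing, floor of 5", {
  # a population whose 90% crossing is at the very first grid point (11)
  pop <- fast_population(gap = 20)
  init <- choose_initial_size(pop, reps = 30, seed = 1)
  expect_equal(init, 9)  # floor guard 3k
  # rule arithmetic on a known crossing (570 -> 190, 300 -> 100)
  expect_equal(5 * floor(round(570 / 3) / 5), 190)
  expect_equal(5 * floor(round(300 / 3) / 5), 100)
})

test_that("pilot selection predicates hold on the returned sample", {
  pop <- build_population("Ba", c(100, 99.2, 98.4), 16, n_per_group = 3000,
                          seed = 21)
  pil <- select_pilot_sample(pop, 60, expect_normal = "Norm", seed = 5)
  s <- pil$groups
  expect_equal(sum(lengths(s)), 60)
  expect_gte(kruskal_wallis(s)$p_value, 0.05)
  expect_gte(kwpower:::classical_anova_p(s), 0.05)
  expect_true(all(vapply(s, function(g) shapiro.test(g)$p.value, 0) >= 0.05))
  # relaxed path only requires KW non-significance
  pil2 <- select_pilot_sample(pop, 60, expect_normal = "KruskalOnly",
                              seed = 6)
  expect_gte(kruskal_wallis(pil2$groups)$p_value, 0.05)
  # determinism
  pil3 <- select_pilot_sample(pop, 60, expect_normal = "Norm", seed = 5)
  expect_identical(pil$groups, pil3$groups)
})

test_that("Not-norm pilot selection transforms to normality", {
  pop <- build_population("B3b", c(100, 99.2, 98.4), 16, n_per_group = 3000,
                          seed = 22)
  expect_identical(pop$spec$expect_normal, "Not-norm")
  pil <- select_pilot_sample(pop, 75, seed = 7)
  expect_false(is.null(pil$johnson))
  tx <- lapply(pil$groups, function(g) johnson_transform(pil$johnson, g))
  expect_true(all(vapply(tx, function(g) shapiro.test(g)$p.value, 0) >= 0.05))
})

test_that("run_study bookkeeping: one row per sample and method", {
  cfg <- kw_run_config("custom",
                       group_means = c(0, 1.5, 3), variance = 1,
                       poptypes = c("Ba"), n_per_group = 600,
                       samples_per_population = 2, measure_reps = 1,
                       reps = 30, max_tries = 200,
                       methods = c("KRM", "ANM", "KRTDIV", "KRTDUP", "ANT",
                                   "ANALYTICAL"))
  ds <- run_study(cfg, seed = 42)
  expect_equal(nrow(ds), 2 + 2 * 4)  # 2 MEASURE rows + 2 pilots x 4 methods
  expect_setequal(unique(ds$method),
                  c("KRM", "ANM", "KRTDIV", "KRTDUP", "ANT", "ANALYTICAL"))
  # missing n_at_power if and only if flagged failed
  expect_equal(is.na(ds$n_at_power), ds$failed)
  # reproducibility from the root seed
  ds2 <- run_study(cfg, seed = 42)
  expect_identical(ds, ds2)
  ds3 <- run_study(cfg, seed = 43)
  expect_false(identical(ds$n_at_power, ds3$n_at_power))
})

test_that("KruskalOnly populations skip ANOVA methods in strict runs", {
  cfg <- kw_run_config("custom",
                       group_means = c(0, 1.5, 3), variance = 1,
                       poptypes = c("D1a"), n_per_group = 600,
                       samples_per_population = 1, measure_reps = 1,
                       reps = 30, max_tries = 400, relaxed = FALSE,
                       tol = c(skewness = 0.5, kurtosis = 5),
                       methods = c("KRM", "ANM", "KRTDIV", "ANT"))
  ds <- run_study(cfg, seed = 7)
  expect_true(all(ds$failed[ds$method %in% c("ANM", "ANT")]))
  expect_false(any(ds$failed[ds$method == "KRM"]))
})

test_that("collate summarizes, aligns complete cases, and tests methods", {
  ds <- data.frame(
    run = "x", poptype = "Ba", pop_id = 1,
    sample_id = rep(c("S1", "S2", "S3"), 2),
    method = rep(c("A", "B"), each = 3),
    n_at_power = c(230, 230, 260, 230, 230, NA),
    failed = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE))
  out <- collate(ds, compare = c("A", "B"))
  sm <- out$summary
  expect_equal(sm$median_all[sm$method == "A"], 230)
  expect_equal(sm$mad_all[sm$method == "A"], 0)
  expect_equal(sm$n_all[sm$method == "A"], 3)
  # complete case drops S3 for both methods
  expect_equal(sm$n_cc, c(2, 2))
  expect_equal(out$n_complete, 2)
  # identical method columns: Brown-Mood p near 1
  ds2 <- ds; ds2$n_at_power <- rep(c(230, 240, 260), 2)
  out2 <- collate(ds2, compare = c("A", "B"))
  expect_gt(out2$brown_mood$p_value, 0.9)
  # all-missing methods are excluded with a note
  out3 <- collate(ds, compare = c("A", "B", "C"))
  expect_identical(out3$dropped, "C")
})

test_that("medical CSV loader filters levels and summarizes groups", {
  path <- file.path(tempdir(), "med.csv")
  set.seed(30)
  df <- data.frame(
    sbp = c(rnorm(40, 135, 5), rnorm(50, 132, 5), rnorm(30, 127, 5),
            rnorm(5, 120, 5), NA),
    center = c(rep("1", 40), rep("2", 50), rep("3", 30), rep("4", 5), "1"))
  write.csv(df, path, row.names = FALSE)
  expect_message(pop <- load_medical_csv(path, "sbp", "center",
                                         drop_levels = "4"),
                 "missing")
  expect_length(pop$groups, 3)
  expect_equal(sum(lengths(pop$groups)), 120)
  expect_equal(pop$proportions, c(40, 50, 30) / 120)
  expect_equal(unname(pop$summary["pooled", "n"]), 120)
  expect_error(load_medical_csv(path, "sbp", "center",
                                drop_levels = c("1", "2", "4")),
               "fewer than 2")
  unlink(path)
})
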