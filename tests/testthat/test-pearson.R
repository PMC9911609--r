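test_that("kappa criterion assigns the tabulated Pearson types", {
  # archetype moment pairs and their types
  expect_identical(classify_pearson(0, 3), "0")
  expect_identical(classify_pearson(0, 5), "VII")
  expect_identical(classify_pearson(0, 10), "VII")
  expect_identical(classify_pearson(0, 1.1), "II")
  expect_identical(classify_pearson(1, 10), "IV")
  expect_identical(classify_pearson(2.14, 15), "IV")
  expect_identical(classify_pearson(1, 3), "I")
  expect_identical(classify_pearson(3, 15), "I")
  # exact type V boundary: kappa = 1 at skew 1 solves near kurtosis 4.97,
  # so the rounded (1, 5) label is honored within the boundary tolerance
  expect_identical(classify_pearson(1, 4.97), "V")
  expect_identical(classify_pearson(1, 5), "V")
  # type III line 2*b2 - 3*b1 - 6 = 0: exact at (2.160..., 10)
  expect_identical(classify_pearson(sqrt((2 * 10 - 6) / 3), 10), "III")
  expect_identical(classify_pearson(2.14, 10), "III")
  # strict assignment away from boundaries: kappa in (0,1) gives IV,
  # kappa > 1 gives VI
  strict <- c(typeV = 1e-9, typeIII = 1e-9)
  expect_identical(classify_pearson(1, 6, strict), "IV")
  expect_identical(classify_pearson(1, 4.8, strict), "VI")
})

test_that("infeasible moment pairs are rejected everywhere", {
  expect_error(classify_pearson(2, 3), "infeasible")
  expect_error(moment_spec(0, 1, 2, 4), "infeasible")
  expect_error(sample_pearson(10, 0, 1, 2, 4), "infeasible")
  expect_error(moment_spec(0, -1), "variance")
})

test_that("samplers reproduce their target moments", {
  n <- 2e5
  cases <- list(c(0, 3), c(0, 5), c(1, 5), c(1, 3), c(2.14, 10))
  for (sk in cases) {
    x <- sample_pearson(n, 100, 20, sk[1], sk[2], seed = 42)
    m <- kwpower:::sample_moments(x)
    expect_equal(unname(m["mean"]), 100, tolerance = 0.01)
    expect_equal(unname(m["variance"]), 20, tolerance = 0.02)
    expect_equal(unname(m["skewness"]), sk[1], tolerance = 0.08)
    expect_equal(unname(m["kurtosis"]), sk[2], tolerance = 0.1)
  }
})

test_that("type VII and V parameterizations match their closed forms", {
  # t-kurtosis inversion: kurt = 3 + 6/(nu - 4)
  expect_equal(kwpower:::pearson7_df(5), 7)
  expect_equal(kwpower:::pearson7_df(10), 4 + 6 / 7)
  # inverse-gamma shape from skew = 4 sqrt(a-2)/(a-3)
  a <- kwpower:::pearson5_shape(1)
  expect_equal(4 * sqrt(a - 2) / (a - 3), 1, tolerance = 1e-12)
  expect_equal(a, 19.94, tolerance = 1e-3)
  # implied type V kurtosis at skew 1 is the 4.97 boundary value
  exk <- (30 * a - 66) / ((a - 3) * (a - 4))
  expect_equal(3 + exk, 4.97, tolerance = 0.005)
})

test_that("type IV parameterization integrates to the target moments", {
  # numeric-integration oracle for the angle-space density
  p <- kwpower:::pearson4_params(1, 10)
  phi <- seq(-pi / 2 + 1e-9, pi / 2 - 1e-9, length.out = 5e5)
  lg <- (2 * p$m - 2) * log(cos(phi)) - p$nu * phi
  g <- exp(lg - max(lg))
  w <- g / sum(g)
  x <- tan(phi)
  mu <- sum(w * x)
  m2 <- sum(w * (x - mu)^2)
  expect_equal(sum(w * (x - mu)^3) / m2^1.5, 1, tolerance = 1e-3)
  expect_equal(sum(w * (x - mu)^4) / m2^2, 10, tolerance = 1e-2)
})

test_that("affine maps leave sample skewness and kurtosis unchanged", {
  x <- sample_pearson(5000, 0, 1, 1, 5, seed = 7)
  m1 <- kwpower:::sample_moments(x)
  m2 <- kwpower:::sample_moments(3.7 * x + 11)
  expect_equal(unname(m1["skewness"]), unname(m2["skewness"]),
               tolerance = 1e-10)
  expect_equal(unname(m1["kurtosis"]), unname(m2["kurtosis"]),
               tolerance = 1e-10)
})

test_that("unsupported samplers signal not-implemented", {
  expect_error(sample_pearson(10, 0, 1, 0, 1.5), "not implemented")
})

test_that("build_population hits exact means and is seed-reproducible", {
  pop <- build_population("Ba", c(100, 99, 98), 20, n_per_group = 2000,
                          seed = 3)
  expect_equal(vapply(pop$groups, mean, 0), c(100, 99, 98), tolerance = 1e-9)
  expect_equal(vapply(pop$groups, var, 0), rep(20, 3), tolerance = 1e-9)
  pop2 <- build_population("Ba", c(100, 99, 98), 20, n_per_group = 2000,
                           seed = 3)
  expect_identical(pop$groups, pop2$groups)
  pop3 <- build_population("Ba", c(100, 99, 98), 20, n_per_group = 2000,
                           seed = 4)
  expect_false(identical(pop$groups, pop3$groups))
})

test_that("N-suffix POPtypes force normal moments on G3", {
  spec <- poptype_spec("BbN")
  expect_true(spec$g3_normal)
  expect_equal(spec$kurtosis, 5)
  pop <- build_population("BbN", c(100, 99, 98), 20, n_per_group = 5000,
                          seed = 5)
  # G1/G2 aim at kurtosis 5, G3 at 3 (within the generation tolerance)
  expect_gt(pop$moments[1, "kurtosis"], 4)
  expect_lt(pop$moments[3, "kurtosis"], 3.5)
})

test_that("POPtype labels parse into analysis paths", {
  expect_identical(poptype_spec("Ba")$expect_normal, "Norm")
  expect_identical(poptype_spec("B3a")$expect_normal, "Not-norm")
  expect_identical(poptype_spec("D3b")$expect_normal, "Not-norm")
  expect_identical(poptype_spec("C1a")$expect_normal, "KruskalOnly")
  expect_identical(poptype_spec("D1a")$expect_normal, "KruskalOnly")
  expect_identical(poptype_spec("C1a")$pearson_type, "V")
  expect_identical(poptype_spec("E1a")$pearson_type, "III")
  expect_error(poptype_spec("Zx"), "unrecognized")
})

test_that("population screening rejects null and over-powered cases", {
  # identical-distribution groups: reject on the population-level KW test
  null_pop <- build_population("Ba", c(100, 100, 100), 20,
                               n_per_group = 1000, seed = 11)
  dec <- accept_population(null_pop, initialsizeN = 30, seed = 1)
  expect_false(dec$accept)
  expect_match(paste(dec$reasons, collapse = " "), "KW")
  # moderate-effect population at a pilot size past the crossing: reject
  # on the power bound
  pop <- fast_population(gap = 0.5)
  dec2 <- accept_population(pop, initialsizeN = 120, seed = 2)
  expect_false(dec2$accept)
  expect_match(paste(dec2$reasons, collapse = " "), "power")
  # same population at a small pilot size: accepted
  dec3 <- accept_population(pop, initialsizeN = 9, seed = 3)
  expect_true(dec3$accept)
})

test_that("population CSV round-trip preserves groups", {
  pop <- build_population("Ba", c(10, 11, 12), 4, n_per_group = 200, seed = 8)
  path <- file.path(tempdir(), "pop-test.csv")
  write_population(pop, path)
  back <- read_population(path)
  expect_equal(sort(unlist(back$groups)), sort(unlist(pop$groups)))
  expect_equal(back$spec$label, "Ba")
  unlink(c(path, paste0(path, ".json")))
})
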