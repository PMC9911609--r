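# Shared fixtures, all generated in code.

# three clearly separated groups (KW power 1 at any size)
disjoint_groups <- function(n = 20) {
  list(runif(n, 0, 1), runif(n, 10, 11), runif(n, 20, 21))
}

# a small population with well-separated groups for fast searches
fast_population <- function(n_per_group = 500, gap = 2, sd = 1,
                            seed = 99) {
  kwpower:::with_seed(seed, {
    groups <- lapply(c(0, gap, 2 * gap), function(m) rnorm(n_per_group, m, sd))
    structure(list(groups = groups,
                   group_labels = paste0("G", 1:3),
                   proportions = rep(1 / 3, 3),
                   spec = list(label = "synthetic", expect_normal = "Norm"),
                   moments = do.call(rbind, lapply(groups, kwpower:::sample_moments)),
                   n_per_group = n_per_group, seed = seed),
              class = "kw_population")
  })
}

# brute-force Vargha-Delaney A by pair enumeration (test oracle)
brute_A <- function(x, y) {
  s <- 0
  for (xi in x) for (yj in y) s <- s + (xi > yj) + 0.5 * (xi == yj)
  s / (length(x) * length(y))
}
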