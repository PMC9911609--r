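## Benchmark population archetypes (POPtypes) and finite population
## construction.  A POPtype label encodes a family letter with fixed
## skewness/kurtosis, an optional "3" infix carrying a normalization
## instruction for the analysis path, and an optional "N" suffix meaning
## group G3 gets normal moments (0, 3).

.poptype_base <- data.frame(
  family   = c("Aa", "Ba", "Bb", "Ca", "Cb", "Da", "Db", "Ea", "Eb", "F"),
  skewness = c(0,    0,    0,    1,    1,    0,    1,    2.14, 2.14, 3),
  kurtosis = c(1.1,  3,    5,    5,    3,    10,   10,   10,   15,   15),
  type     = c("II", "0",  "VII", "V", "I",  "VII", "IV", "III", "IV", "I"),
  stringsAsFactors = FALSE)

#' Table of population archetypes
#'
#' @return Data frame of the base archetype families with their
#'   skewness/kurtosis pairs and Pearson types.
#' @export
kw_poptypes <- function() .poptype_base

#' Parse a POPtype label into a population specification
#'
#' Labels look like `"Ba"`, `"C1a"`, `"D3b"`, `"BbN"`: a family letter
#' A-F, an optional variant digit (`3` marks the normalize-before-ANOVA
#' instruction; `1` or absent means none), a variant letter a/b, and an
#' optional `N` suffix forcing normal moments (0, 3) for group G3.
#' The analysis-path flag is derived from the label: normalized variants
#' expect ANOVA on transformed data (`"Not-norm"`), symmetric families with
#' kurtosis at most 5 support plain ANOVA (`"Norm"`), and all others are
#' `"KruskalOnly"`.
#'
#' @param label POPtype code.
#' @return A list with `label`, `skewness`, `kurtosis`, `pearson_type`,
#'   `normalize`, `g3_normal` and `expect_normal`.
#' @examples
#' poptype_spec("D3b")
#' @export
poptype_spec <- function(label) {
  m <- regmatches(label, regexec("^([A-F])([13]?)([ab]?)(N?)$", label))[[1]]
  if (length(m) == 0) stop("unrecognized POPtype label: ", label)
  fam <- paste0(m[2], m[4])
  if (m[2] == "F") fam <- "F"
  row <- .poptype_base[.poptype_base$family == fam, ]
  if (nrow(row) != 1) stop("unrecognized POPtype label: ", label)
  normalize <- m[3] == "3"
  expect <- if (normalize) {
    "Not-norm"
  } else if (row$skewness == 0 && row$kurtosis <= 5) {
    "Norm"
  } else {
    "KruskalOnly"
  }
  list(label = label, skewness = row$skewness, kurtosis = row$kurtosis,
       pearson_type = row$type, normalize = normalize,
       g3_normal = m[5] == "N", expect_normal = expect)
}

#' Build a finite benchmark population
#'
#' Generates one value store per group from the Pearson family of the
#' POPtype, then affinely standardizes each group to its exact target mean
#' and variance (affine maps leave skewness and kurtosis unchanged).  Each
#' group is regenerated until its empirical skewness and kurtosis fall
#' within tolerance of the specification; for an `"N"`-suffix POPtype,
#' group G3 targets normal moments (0, 3).
#'
#' @param poptype POPtype label (see [poptype_spec()]) or a spec list.
#' @param group_means numeric vector of group means (one per group).
#' @param variance common group variance.
#' @param n_per_group values per group (default 10000).
#' @param tol named tolerances `c(skewness =, kurtosis =)` on the empirical
#'   moments (defaults 0.1 and 0.25).
#' @param max_tries regeneration cap per group.
#' @param seed integer seed; the same seed reproduces the population
#'   exactly.
#' @param on_fail `"error"` (default) raises a generation-failure error
#'   carrying best-attempt diagnostics; `"best"` keeps the best attempt and
#'   flags it.
#' @return An object of class `kw_population`: `groups` (list of numeric
#'   vectors), `group_labels`, `proportions`, `spec`, `moments` (empirical,
#'   per group), `seed`.
#' @export
build_population <- function(poptype, group_means, variance,
                             n_per_group = 10000,
                             tol = c(skewness = 0.1, kurtosis = 0.25),
                             max_tries = 500, seed = NULL,
                             on_fail = c("error", "best")) {
  on_fail <- match.arg(on_fail)
  spec <- if (is.character(poptype)) poptype_spec(poptype) else poptype
  k <- length(group_means)
  stopifnot(k >= 2, variance > 0, n_per_group >= 10)
  tol_s <- tol[["skewness"]]; tol_k <- tol[["kurtosis"]]
  groups <- vector("list", k)
  mom <- vector("list", k)
  flagged <- FALSE
  for (j in seq_len(k)) {
    g3n <- spec$g3_normal && j == k
    sk <- if (g3n) 0 else spec$skewness
    ku <- if (g3n) 3 else spec$kurtosis
    best <- NULL; best_dev <- Inf
    found <- FALSE
    for (try in seq_len(max_tries)) {
      x <- sample_pearson(n_per_group, 0, 1, sk, ku,
                          seed = derive_seed(seed %||% 0, j, try))
      m <- sample_moments(x)
      dev <- max(abs(m["skewness"] - sk) / tol_s,
                 abs(m["kurtosis"] - ku) / tol_k)
      if (dev < best_dev) { best_dev <- dev; best <- x }
      if (dev <= 1) { found <- TRUE; break }
    }
    if (!found) {
      if (on_fail == "error") {
        stop(sprintf(paste0("group %d: empirical moments not within ",
                            "tolerance after %d tries (best deviation ",
                            "%.2f x tolerance)"), j, max_tries, best_dev))
      }
      flagged <- TRUE
    }
    x <- best
    ## exact mean/variance by affine standardization
    x <- group_means[j] + (x - mean(x)) / sd(x) * sqrt(variance)
    groups[[j]] <- x
    mom[[j]] <- sample_moments(x)
  }
  structure(list(groups = groups,
                 group_labels = paste0("G", seq_len(k)),
                 proportions = rep(1 / k, k),
                 spec = c(spec, list(group_means = group_means,
                                     variance = variance,
                                     tol = c(skewness = tol_s, kurtosis = tol_k))),
                 moments = do.call(rbind, mom),
                 n_per_group = n_per_group,
                 tolerance_flagged = flagged,
                 seed = seed),
            class = "kw_population")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.kw_population <- function(x, ...) {
  cat("Benchmark population '", x$spec$label %||% "custom", "': ",
      length(x$groups), " groups x ", x$n_per_group, " values\n", sep = "")
  print(round(x$moments, 3))
  invisible(x)
}

#' Population acceptance check
#'
#' A candidate population is accepted iff (a) the Kruskal-Wallis test
#' across its groups is significant at `alphaPOP`; (b) the Monte-Carlo
#' Kruskal-Wallis power of `reps` samples of total size `initialsizeN`
#' does not exceed `target_power`; and (c) for populations whose analysis
#' path expects ANOVA (plain or on transformed data), the same power bound
#' holds for the White-adjusted ANOVA.
#'
#' @param pop a `kw_population`.
#' @param alphaPOP significance level for the population-level test.
#' @param alpha sample-level significance level used in the power checks.
#' @param target_power power that must not be exceeded at `initialsizeN`.
#' @param initialsizeN pilot total sample size (>= 3 per group).
#' @param reps Monte-Carlo samples for the power checks (default 100).
#' @param seed integer seed.
#' @return List with `accept` (logical), `reasons` (character), and the
#'   computed `kw_p`, `kw_power`, `anova_power`.
#' @export
accept_population <- function(pop, alphaPOP = 0.05, alpha = 0.05,
                              target_power = 0.8, initialsizeN,
                              reps = 100, seed = NULL) {
  stopifnot(inherits(pop, "kw_population"),
            initialsizeN >= 3 * length(pop$groups))
  reasons <- character()
  kw_p <- kruskal_wallis(pop$groups)$p_value
  if (!(kw_p < alphaPOP)) {
    reasons <- c(reasons, "population groups not significantly different (KW)")
  }
  gen <- generator_population(pop)
  q <- power_query(test = "KW", alpha = alpha, target_power = target_power,
                   reps = reps, n_start = initialsizeN,
                   proportions = pop$proportions)
  kw_pow <- estimate_power(gen, initialsizeN, q, seed = derive_seed(seed %||% 0, 101))
  if (kw_pow$power > target_power) {
    reasons <- c(reasons, "KW power at initialsizeN already above target power")
  }
  an_pow <- NA_real_
  expect <- pop$spec$expect_normal %||% "Norm"
  if (expect %in% c("Norm", "Not-norm")) {
    qa <- q; qa$test <- "ANOVA_White"
    an <- estimate_power(gen, initialsizeN, qa, seed = derive_seed(seed %||% 0, 102))
    an_pow <- an$power
    if (an_pow > target_power) {
      reasons <- c(reasons, "ANOVA power at initialsizeN already above target power")
    }
  }
  list(accept = length(reasons) == 0, reasons = reasons,
       kw_p = kw_p, kw_power = kw_pow$power, anova_power = an_pow)
}

#' Write or read a population as long-format CSV plus JSON sidecar
#'
#' The CSV has columns `group,value`; the sidecar (same path with
#' `.json` appended) stores the specification, seed and tolerances.
#'
#' @param pop a `kw_population`.
#' @param path CSV path.
#' @return `read_population` returns a `kw_population` (sidecar optional).
#' @export
write_population <- function(pop, path) {
  df <- data.frame(
    group = rep(pop$group_labels, lengths(pop$groups)),
    value = unlist(pop$groups, use.names = FALSE))
  write.csv(df, path, row.names = FALSE)
  side <- pop$spec
  side$seed <- pop$seed
  side$n_per_group <- pop$n_per_group
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_population
#' @export
read_population <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("group", "value") %in% names(df)))
  groups <- split(df$value, df$group)
  spec <- NULL
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    spec <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  }
  structure(list(groups = unname(groups),
                 group_labels = names(groups),
                 proportions = lengths(groups) / nrow(df),
                 spec = spec,
                 moments = do.call(rbind, lapply(unname(groups), sample_moments)),
                 n_per_group = max(lengths(groups)),
                 seed = spec$seed %||% NULL),
            class = "kw_population")
}
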