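## Study orchestration: population build -> pilot-sample selection -> TRIAL
## predictions and MEASURE estimates -> collation.  One datastore row per
## (sample, method).

#' Built-in run configurations
#'
#' Returns the settings of the four simulation runs: group means, common
#' variance, the POPtype list, selection mode, and search settings.  Any
#' field can be overridden via `...`.
#'
#' @param name one of `"run_one"`, `"run_one_relaxed"`, `"run_two"`,
#'   `"run_three"`, or `"custom"`.
#' @param ... overrides (e.g. `samples_per_population = 5`,
#'   `n_per_group = 2000`).
#' @return A `kw_run_config` list.
#' @export
kw_run_config <- function(name = c("run_three", "run_one", "run_one_relaxed",
                                   "run_two", "custom"), ...) {
  name <- match.arg(name)
  base <- switch(name,
    run_one = list(
      group_means = c(100, 99.5, 99), variance = 5,
      poptypes = c("Ba", "Bb", "B3a", "B3b", "BaN", "BbN", "C1a", "C1aN",
                   "C3a", "D1a", "D1aN", "D1b", "D1bN", "D3a", "D3b",
                   "E1a", "E1aN", "E3a"),
      relaxed = FALSE),
    run_one_relaxed = list(
      group_means = c(100, 99.5, 99), variance = 5,
      poptypes = c("Ba", "Bb", "B3a", "B3b", "BaN", "BbN", "C1a", "C1aN",
                   "C3a", "D1a", "D1aN", "D1b", "D1bN", "D3a", "D3b"),
      relaxed = TRUE),
    run_two = list(
      group_means = c(100, 99.7, 99.45), variance = 5,
      poptypes = c("Ba", "Bb", "B3a", "B3b", "BaN", "BbN", "C1a", "C1aN",
                   "C3a", "D1b", "D1bN", "D3b"),
      relaxed = FALSE),
    run_three = list(
      group_means = c(100, 99, 98), variance = 20,
      poptypes = c("Ba", "Bb", "B3a", "B3b", "BaN", "BbN"),
      relaxed = FALSE),
    custom = list(group_means = NULL, variance = NULL, poptypes = NULL,
                  relaxed = FALSE))
  cfg <- utils::modifyList(
    c(base, list(
      name = name, alpha = 0.05, alphaPOP = 0.05, target_power = 0.8,
      samples_per_population = 10, measure_reps = 1, n_per_group = 10000,
      reps = 100, step = 5, max_tries = 500,
      tol = c(skewness = 0.1, kurtosis = 0.25),
      methods = c("KRTDIV", "KRTDUP", "ANT", "ANALYTICAL", "KRM", "ANM"))),
    list(...))
  structure(cfg, class = "kw_run_config")
}

#' Choose the pilot sample size for a population
#'
#' Runs a preliminary measured Kruskal-Wallis sample-size search at 90%
#' power and returns one third of the crossing, rounded down to a multiple
#' of 5 (floor 3 per group), the rule used to set `initialsizeN`.
#'
#' @param pop a `kw_population`.
#' @param alpha significance level.
#' @param reps Monte-Carlo samples per candidate size.
#' @param step scan step.
#' @param seed integer seed.
#' @return Integer pilot total size.
#' @export
choose_initial_size <- function(pop, alpha = 0.05, reps = 100, step = 5,
                                seed = NULL) {
  k <- length(pop$groups)
  n0 <- 5 * ceiling((3 * k + 1) / 5) + 1  # small multiple-of-5 grid start
  q <- power_query(test = "KW", alpha = alpha, target_power = 0.9,
                   reps = reps, n_start = n0, step = step,
                   proportions = pop$proportions,
                   max_n = min(lengths(pop$groups) / pop$proportions))
  est <- measured_sample_size(pop, q, seed = seed)
  if (est$failed) stop("preliminary 90%-power measured search failed")
  max(3 * k, 5 * floor(round(est$n_at_power / 3) / 5))
}

#' Select a pilot sample satisfying the selection predicate
#'
#' Draws samples of total size `initialsizeN` from the population (without
#' replacement per draw, rounded group proportions) until one satisfies:
#' Kruskal-Wallis p >= alpha; and, depending on the analysis path, ANOVA
#' p >= alpha with every group Shapiro-normal (`"Norm"`), the same on
#' Johnson-transformed values (`"Not-norm"`), or nothing further
#' (`"KruskalOnly"` / relaxed selection).
#'
#' @param pop a `kw_population`.
#' @param initialsizeN pilot total size.
#' @param expect_normal `"Norm"`, `"Not-norm"` or `"KruskalOnly"`; defaults
#'   to the population's analysis path.
#' @param alpha significance level for the non-significance conditions.
#' @param shapiro_alpha per-group normality threshold (default 0.05).
#' @param max_tries rejection-sampling cap.
#' @param seed integer seed.
#' @return List with `groups`, `tries`, and `johnson` (the transformation
#'   fit used, for the Not-norm path).
#' @export
select_pilot_sample <- function(pop, initialsizeN, expect_normal = NULL,
                                alpha = 0.05, shapiro_alpha = 0.05,
                                max_tries = 2000, seed = NULL) {
  expect_normal <- expect_normal %||% pop$spec$expect_normal %||% "Norm"
  gen <- generator_population(pop)
  for (try in seq_len(max_tries)) {
    s <- gen(initialsizeN, seed = derive_seed(seed %||% 0, try))
    if (.kw_p(s)[2] < alpha) next
    if (expect_normal == "KruskalOnly") {
      return(list(groups = s, tries = try, johnson = NULL))
    }
    jf <- NULL
    vals <- s
    if (expect_normal == "Not-norm") {
      jf <- tryCatch(johnson_fit(unlist(s, use.names = FALSE)),
                     error = function(e) NULL)
      if (is.null(jf)) next
      vals <- lapply(s, function(g) johnson_transform(jf, g))
      if (any(!vapply(vals, function(v) all(is.finite(v)), TRUE))) next
    }
    if (classical_anova_p(vals) < alpha) next
    swp <- vapply(vals, function(g) {
      if (length(unique(g)) < 3) return(0)
      shapiro.test(g)$p.value
    }, 0)
    if (any(swp < shapiro_alpha)) next
    return(list(groups = s, tries = try, johnson = jf))
  }
  stop("pilot-sample selection failed within ", max_tries, " tries")
}

## classical one-way ANOVA p-value (closed form, used in pilot selection)
classical_anova_p <- function(groups) {
  k <- length(groups)
  n <- lengths(groups)
  N <- sum(n)
  mns <- vapply(groups, mean, 0)
  gm <- sum(n * mns) / N
  ssb <- sum(n * (mns - gm)^2)
  ssw <- sum(mapply(function(g, m) sum((g - m)^2), groups, mns))
  if (ssw == 0) return(if (ssb == 0) 1 else 0)
  Fstat <- (ssb / (k - 1)) / (ssw / (N - k))
  pf(Fstat, k - 1, N - k, lower.tail = FALSE)
}

#' Run a full study
#'
#' For each POPtype in the configuration: builds and screens a population,
#' chooses `initialsizeN`, selects pilot samples, and runs the requested
#' method codes (KRTDIV/KRTDUP/ANT/ANALYTICAL per pilot; KRM/ANM per
#' population).  ANT and ANM are skipped (recorded as missing) for
#' `KruskalOnly` populations in non-relaxed runs.  Individual failures are
#' recorded as missing rows, never aborting the run.
#'
#' @param config a `kw_run_config`.
#' @param seed root integer seed; the whole run is reproducible from it.
#' @param verbose print progress lines.
#' @return A data.frame datastore, one row per (sample, method), with
#'   columns `run`, `poptype`, `pop_id`, `sample_id`, `method`,
#'   `n_at_power`, `power_at_n`, `min_effect`, `failed`, `initialsizeN`,
#'   and per-group sample means/variances.
#' @export
run_study <- function(config, seed = 1, verbose = FALSE) {
  stopifnot(inherits(config, "kw_run_config"))
  rows <- list()
  k <- length(config$group_means)
  say <- function(...) if (verbose) message(sprintf(...))
  for (ip in seq_along(config$poptypes)) {
    ty <- config$poptypes[ip]
    pop <- tryCatch(
      build_population(ty, config$group_means, config$variance,
                       n_per_group = config$n_per_group,
                       tol = config$tol, max_tries = config$max_tries,
                       seed = derive_seed(seed, ip, 1)),
      error = function(e) NULL)
    if (is.null(pop)) { say("%s: population generation failed", ty); next }
    init <- tryCatch(
      choose_initial_size(pop, alpha = config$alpha, reps = config$reps,
                          step = config$step,
                          seed = derive_seed(seed, ip, 2)),
      error = function(e) NULL)
    if (is.null(init)) { say("%s: preliminary search failed", ty); next }
    acc <- accept_population(pop, alphaPOP = config$alphaPOP,
                             alpha = config$alpha,
                             target_power = config$target_power,
                             initialsizeN = init, reps = config$reps,
                             seed = derive_seed(seed, ip, 3))
    if (!acc$accept) {
      say("%s: population rejected (%s)", ty,
          paste(acc$reasons, collapse = "; "))
      next
    }
    expect <- if (config$relaxed) "KruskalOnly" else pop$spec$expect_normal
    skip_anova <- !config$relaxed && pop$spec$expect_normal == "KruskalOnly"
    say("%s: initialsizeN = %d", ty, init)

    mk_row <- function(sample_id, method, est, sample = NULL) {
      mom <- if (!is.null(sample)) {
        c(vapply(sample, mean, 0), vapply(sample, var, 0))
      } else {
        c(vapply(pop$groups, mean, 0), vapply(pop$groups, var, 0))
      }
      names(mom) <- c(paste0("mean", seq_len(k)), paste0("var", seq_len(k)))
      as.data.frame(c(
        list(run = config$name, poptype = ty, pop_id = ip,
             sample_id = sample_id, method = method,
             n_at_power = est$n_at_power %||% NA_integer_,
             power_at_n = est$power_at_n %||% NA_real_,
             min_effect = est$min_effect %||% NA_real_,
             failed = isTRUE(est$failed), initialsizeN = init),
        as.list(mom)))
    }
    missing_row <- function(sample_id, method, sample = NULL) {
      mk_row(sample_id, method,
             list(n_at_power = NA_integer_, power_at_n = NA_real_,
                  min_effect = NA_real_, failed = TRUE), sample)
    }

    q0 <- power_query(test = "KW", alpha = config$alpha,
                      target_power = config$target_power,
                      reps = config$reps, n_start = init + 1,
                      step = config$step, proportions = pop$proportions,
                      max_n = 20 * (init + 1))
    ## MEASURE (per population)
    for (im in seq_len(config$measure_reps)) {
      if ("KRM" %in% config$methods) {
        est <- measured_sample_size(pop, q0, seed = derive_seed(seed, ip, 4, im))
        rows <- c(rows, list(mk_row(paste0("M", im), "KRM", est)))
      }
      if ("ANM" %in% config$methods) {
        if (skip_anova) {
          rows <- c(rows, list(missing_row(paste0("M", im), "ANM")))
        } else {
          qa <- q0; qa$test <- "ANOVA_White"
          est <- measured_sample_size(pop, qa, seed = derive_seed(seed, ip, 5, im))
          rows <- c(rows, list(mk_row(paste0("M", im), "ANM", est)))
        }
      }
    }
    ## TRIAL (per pilot sample)
    for (is in seq_len(config$samples_per_population)) {
      pil <- tryCatch(
        select_pilot_sample(pop, init, expect_normal = expect,
                            alpha = config$alpha,
                            seed = derive_seed(seed, ip, 6, is)),
        error = function(e) NULL)
      if (is.null(pil)) {
        for (m in intersect(config$methods,
                            c("KRTDIV", "KRTDUP", "ANT", "ANALYTICAL"))) {
          rows <- c(rows, list(missing_row(paste0("S", is), m)))
        }
        next
      }
      s <- pil$groups
      if ("KRTDIV" %in% config$methods) {
        est <- predicted_kw(s, "div", q0, seed = derive_seed(seed, ip, 7, is))
        rows <- c(rows, list(mk_row(paste0("S", is), "KRTDIV", est, s)))
      }
      if ("KRTDUP" %in% config$methods) {
        est <- predicted_kw(s, "dup", q0, seed = derive_seed(seed, ip, 8, is))
        rows <- c(rows, list(mk_row(paste0("S", is), "KRTDUP", est, s)))
      }
      if ("ANT" %in% config$methods) {
        if (skip_anova) {
          rows <- c(rows, list(missing_row(paste0("S", is), "ANT", s)))
        } else {
          est <- predicted_anova(s, q0, seed = derive_seed(seed, ip, 9, is))
          rows <- c(rows, list(mk_row(paste0("S", is), "ANT", est, s)))
        }
      }
      if ("ANALYTICAL" %in% config$methods) {
        est <- tryCatch({
          an <- analytical_anova_n(vapply(s, mean, 0),
                                   mean(vapply(s, var, 0)),
                                   alpha = config$alpha,
                                   target_power = config$target_power,
                                   proportions = pop$proportions)
          list(n_at_power = an$total, power_at_n = an$power,
               min_effect = min_effect_size(s), failed = FALSE)
        }, error = function(e) NULL)
        rows <- c(rows, list(
          if (is.null(est)) missing_row(paste0("S", is), "ANALYTICAL", s)
          else mk_row(paste0("S", is), "ANALYTICAL", est, s)))
      }
    }
  }
  if (length(rows) == 0) {
    stop("run produced no records (all populations failed or were rejected)")
  }
  do.call(rbind, rows)
}

#' Collate a datastore into per-method summaries
#'
#' Medians and raw MADs (constant 1) of `n_at_power` per method, in two
#' variants: complete-case across the compared methods (a sample
#' contributes only if all compared methods are non-missing for it) and
#' all-available.  Methods are compared pairwise by Brown-Mood median
#' tests with Bonferroni adjustment.
#'
#' @param records datastore data.frame from [run_study()].
#' @param compare method codes to compare (default all present).
#' @return A `kw_collated` list: `summary` data.frame and `brown_mood`
#'   (global test plus pairwise table), or `NULL` tests when fewer than 2
#'   methods have data.
#' @export
collate <- function(records, compare = NULL) {
  stopifnot(nrow(records) > 0)
  compare <- compare %||% unique(records$method)
  present <- intersect(compare, unique(records$method))
  dropped <- setdiff(compare, present)
  sub <- records[records$method %in% present, ]
  key <- interaction(sub$run, sub$poptype, sub$pop_id, sub$sample_id,
                     drop = TRUE)
  wide <- tapply(sub$n_at_power, list(key, sub$method), function(v) v[1])
  wide <- wide[, present, drop = FALSE]
  cc <- wide[stats::complete.cases(wide), , drop = FALSE]
  summarize <- function(v) {
    v <- v[!is.na(v)]
    if (length(v) == 0) return(c(median = NA, mad = NA, n = 0))
    mm <- median_mad(v)
    c(median = unname(mm["median"]), mad = unname(mm["mad"]), n = length(v))
  }
  sm <- data.frame(
    method = present,
    t(vapply(present, function(m) summarize(cc[, m]), numeric(3))),
    t(vapply(present, function(m) summarize(wide[, m]), numeric(3))))
  names(sm) <- c("method", "median_cc", "mad_cc", "n_cc",
                 "median_all", "mad_all", "n_all")
  rownames(sm) <- NULL
  bm <- NULL
  usable <- present[colSums(!is.na(cc)) > 0]
  if (nrow(cc) > 0 && length(usable) >= 2) {
    bm <- brown_mood_median(lapply(usable, function(m) cc[, m]))
    bm$methods <- usable
  }
  structure(list(summary = sm, brown_mood = bm, dropped = dropped,
                 n_complete = nrow(cc)),
            class = "kw_collated")
}

#' @export
print.kw_collated <- function(x, ...) {
  cat("Collated sample-size estimates (complete-case n =", x$n_complete,
      ")\n")
  print(x$summary, digits = 4)
  if (!is.null(x$brown_mood)) {
    cat("Brown-Mood global: chi2 =",
        format(x$brown_mood$statistic, digits = 4),
        ", df =", x$brown_mood$df,
        ", p =", format(x$brown_mood$p_value, digits = 3), "\n")
  }
  if (length(x$dropped)) {
    cat("Excluded (no data):", paste(x$dropped, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Load a medical-study dataset as a population
#'
#' Reads a CSV with one continuous value column and one group column,
#' drops missing values (with a count message) and the listed group
#' levels, and returns a `kw_population` whose proportions come from the
#' data.  A per-group and pooled summary block (mean, median, variance,
#' raw MAD) is attached for comparison with published descriptive tables.
#'
#' @param path CSV file path.
#' @param value_col,group_col column names.
#' @param drop_levels group levels to remove (e.g. small categories).
#' @return A `kw_population` with a `summary` element.
#' @export
load_medical_csv <- function(path, value_col, group_col,
                             drop_levels = NULL) {
  stopifnot(file.exists(path))
  df <- read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c(value_col, group_col) %in% names(df)))
  v <- df[[value_col]]; g <- as.character(df[[group_col]])
  keep <- !is.na(v) & !is.na(g)
  if (any(!keep)) message(sum(!keep), " rows with missing values dropped")
  v <- v[keep]; g <- g[keep]
  keep2 <- !(g %in% as.character(drop_levels))
  v <- v[keep2]; g <- g[keep2]
  groups <- split(v, g)
  if (length(groups) < 2) stop("fewer than 2 groups after filtering")
  summ <- lapply(c(groups, list(pooled = v)), function(x) {
    mm <- median_mad(x)
    c(n = length(x), mean = mean(x), median = unname(mm["median"]),
      variance = var(x), mad = unname(mm["mad"]))
  })
  structure(list(groups = unname(groups),
                 group_labels = names(groups),
                 proportions = unname(lengths(groups)) / length(v),
                 spec = list(label = "medical", source = path,
                             expect_normal = "Norm"),
                 moments = do.call(rbind, lapply(unname(groups),
                                                 sample_moments)),
                 n_per_group = max(lengths(groups)),
                 summary = do.call(rbind, summ),
                 seed = NULL),
            class = "kw_population")
}
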