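Package: kwpower
Title: Monte-Carlo Kruskal-Wallis Power Studies Using Bernstein Transformation Fits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Sample-size estimation for multi-group comparisons by the
    Kruskal-Wallis test, using Monte-Carlo power curves built from monotone
    Bernstein-basis transformation models ("most likely transformation" fits)
    of pilot data.  Includes the comparator methods needed for benchmarking:
    Monte-Carlo heteroskedasticity-robust (White-adjusted) ANOVA, analytical
    noncentral-F ANOVA power, and measured power by resampling a finite
    population.  A Pearson-system simulation harness generates benchmark
    populations with specified skewness and kurtosis, and a study runner
    orchestrates population construction, pilot-sample selection, prediction
    and collation with Brown-Mood median-test comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    sandwich,
    lmtest,
    pracma
Config/testthat/edition: 3
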