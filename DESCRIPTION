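Package: stepcnv
Title: Stepwise Bayesian Detection of Copy Number Variants from Array
    Intensity and Sequencing Read Depth
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects copy number variants (CNVs) from genomic copy-number
    signals - array-CGH log2 ratios or mean-centered sequencing read depth -
    with a stepwise Bayesian change-point model. The underlying spectrum is a
    sum of N rectangular steps, each with a start, width and amplitude, under
    additive Gaussian noise. A Gibbs sampler with conjugate full conditionals
    draws from the joint posterior of segment positions, amplitudes and the
    noise variance, yielding point estimates and 95% credible intervals for
    every breakpoint and amplitude. The number of CNVs is chosen by Bayes
    factors computed from a stabilized (defensive-mixture) harmonic-mean
    estimator of the marginal likelihood. Includes a synthetic-data generator,
    read-depth windowing utilities with a discrete (multinomial) amplitude
    prior, coverage-downsampling experiments, chunked whole-genome processing,
    and broom-style tidiers plus ggplot2 visualisations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
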