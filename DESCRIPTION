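Package: stridedep
Title: Stride-to-Stride Dependence of Leg Stiffness in Running
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying the variability and serial dependence of
    human leg stiffness across running strides. Provides a planar
    spring-loaded inverted pendulum (SLIP) gait simulator with a latent
    autoregressive per-stride stiffness process, stance-phase segmentation of
    treadmill marker and force recordings, per-stride leg-stiffness
    estimation (peak-force/compression and no-intercept least squares on the
    spring-mass force model), stride-independence tests (per-lag Yule test on
    the sample autocorrelation function, Ljung-Box portmanteau test,
    Bonferroni adjustment, Grubbs outlier screen), the variance-to-variance
    ratio correcting the variance of a mean for serial correlation, and
    random-intercept linear mixed-effects models of stiffness on stride
    number and treadmill speed.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    data.table,
    jsonlite,
    lme4,
    lmerTest,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    ggplot2,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
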