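Package: metqg
Title: Quantitative Genetics and Genomic Prediction for Multi-Environment
    Yield Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the retrospective quantitative-genetic analysis of
    multi-environment plant breeding yield trials: simulation of genotyped
    breeding cohorts evaluated in alpha-lattice designs with known genetic
    truth; marker quality control, k-nearest-neighbour imputation and
    genomic relationship matrices; an average-information REML and Gibbs
    sampling engine for Gaussian mixed models with arbitrary covariance
    kernels; best linear unbiased estimates of line means from lattice
    trials; marker-based narrow-sense heritabilities, genetic correlations
    between environments, correlated-response ratios and site clustering;
    and reaction-norm genotype-by-environment genomic prediction of
    target-environment yield from selection-environment yield.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ape,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    lme4,
    withr
Config/testthat/edition: 3
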