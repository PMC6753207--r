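Package: mrivw
Title: Two-Sample Mendelian Randomization from GWAS Summary Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for two-sample Mendelian randomization from genome-wide
    association study (GWAS) summary statistics: instrument selection
    (genome-wide significance filtering, greedy linkage-disequilibrium
    pruning with lead-SNP retention, proxy variant substitution), allele
    harmonization between exposure and outcome studies, per-variant Wald
    ratios pooled by fixed-effect inverse-variance weighting, MR-Egger
    regression with the directional-pleiotropy intercept test, Cochran's Q
    heterogeneity, leave-one-out re-estimation, funnel-plot data export,
    and Bayesian false-discovery assessment over a grid of priors. Includes
    a generator of synthetic two-sample summary statistics with known
    causal structure so every stage of the pipeline can be exercised and
    calibrated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    metafor,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
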