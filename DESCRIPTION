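Package: gbsmix
Title: Relative Abundance Quantification of Strain Mixtures from
    Multispecies Genotyping-by-Sequencing
Version: 0.1.0
Authors@R:
    person("gbsmix", "developers", email = "gbsmix@example.org",
           role = c("aut", "cre"))
Description: Quantifies the relative abundances of closely related strains
    in mixed samples sequenced with multispecies genotyping-by-sequencing
    (msGBS). Builds a meta-reference of strain-labelled genomic clusters
    from monoclonal read sets, filters homologous clusters that attract
    cross-strain reads, maps mixture reads with multi-mapping, converts
    mapped read counts to calibrated relative abundances using
    equal-proportion calibration samples, and benchmarks the estimates
    against known mock compositions and light-microscopy counts. Includes
    a restriction-digest read simulator (double digest, UMIs, PCR
    duplicates, per-strain yield biases) so the whole workflow is testable
    on synthetic data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
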