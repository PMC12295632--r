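Package: swimprot
Title: Behavioral Phenotyping and Label-Free Proteomics for Larval
    Zebrafish Neurotoxicity Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies larval zebrafish swim behavior from tracked
    trajectories (velocity-threshold activity classification, burst
    ("bolt") segmentation, light/dark epoch responses, per-second
    locomotor profiles) and analyses label-free quantification (LFQ)
    proteomics matrices (replicate-consistency filtering, log2
    normalization, Welch t-tests with Benjamini-Hochberg correction,
    hypergeometric gene-set enrichment).  Includes seeded stochastic
    generators for swim trajectories and LFQ matrices with known ground
    truth, end-to-end pipeline drivers, and ggplot2 visualisations.
    Designed for toxicant-exposure assays such as the
    1-methyl-4-phenylpyridinium (MPP+) Parkinsonism model.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
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
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
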