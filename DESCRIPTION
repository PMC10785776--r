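Package: silacturnover
Title: SILAC Pulse-Chase Protein Turnover and IP-MS Interactome Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Downstream analysis of SILAC pulse-chase LC-MS/MS experiments in
    postmitotic cells: peptide-level labeling-efficiency summaries, day-30
    anchored protein turnover ratios with the associated filtering rules,
    cross-genotype persisting-protein calls with paired and peptide-level
    statistics, first-order decay-rate (half-life) fitting, and spectral-count
    based immunoprecipitation interactome filtering (bait normalization, IgG
    exclusivity, ratio thresholding, replicate concordance, genotype
    partitioning and enrichment testing). Includes a synthetic-data generator
    that emulates the statistical structure of both experiment types with
    known ground truth, strict tabular input validation, and a deterministic
    end-to-end pipeline with a digest manifest.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    readr,
    rlang,
    jsonlite,
    digest,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
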