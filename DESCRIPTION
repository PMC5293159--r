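Package: cofrac
Title: Dynamic Co-Fractionation Interactomics and N-Terminome Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end analysis pipeline for protein correlation profiling
    (PCP-SILAC) co-fractionation experiments over size-exclusion chromatography
    or blue-native PAGE, paired with a TAILS N-terminome analysis. Deconvolves
    per-protein elution chromatograms into Gaussian features, aligns features
    across biological replicates, scores candidate protein pairs by co-elution,
    calibrates interaction networks to target precisions against a gold-standard
    complex database, assembles complexes by Markov clustering, tests
    condition-induced feature changes with Shannon evenness statistics at the
    peptide level, models bimodal N-terminus ratio distributions with a Gaussian
    mixture, and correlates proteolytic cleavage with interactome change. A
    ground-truthed synthetic-data generator emulating the full study design
    makes every stage testable without raw mass-spectrometry data.
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
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    Biostrings,
    igraph,
    jsonlite,
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
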