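Package: selexr
Title: Analysis and Simulation of Capture-SELEX Sequencing Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analyzing high-throughput sequencing data from in vitro
    selection (SELEX) of RNA aptamers, with an emphasis on multiplexed
    Capture-SELEX performed on riboswitch-derived scaffold pools. Provides
    scaffold definition and pool diversity accounting, doped (partially
    degenerate) reselection pool construction, paired-end read merging by
    overlap, exact-match read tallying into ranked abundance tables, greedy
    rank-seeded similarity clustering with constant-region masking,
    cross-generation class enrichment tracking, detection of unintended
    capture-oligonucleotide complementarity ("selfish" sequences),
    elution-profile summaries, and dissociation-constant estimation from
    titration band intensities by sigmoidal (Hill) fitting. A stochastic
    Capture-SELEX round simulator generates synthetic pools, paired-end reads,
    and titration curves so every stage of the pipeline can be tested without
    experimental data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    purrr,
    rlang,
    stats,
    stringi,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
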