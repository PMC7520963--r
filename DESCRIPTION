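Package: plastaudit
Title: Evaluation of Chloroplast Genome Assemblies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to evaluate chloroplast (plastid) genome assemblies.
    Scores candidate assemblies against a reference with a four-component
    0-100 score (completeness, correctness, repeat resolution, continuity)
    derived from bidirectional alignment coverage; detects the inverted
    repeat pair and the quadripartite LSC/IRa/SSC/IRb structure of a
    circular plastome; rotates assemblies into a canonical layout;
    classifies assembly success with and without a reference, including
    F1-based calibration of reference-free cutoffs; and simulates perfect
    paired-end reads from organelle-enriched genome mixtures so the whole
    pipeline can be tested on synthetic data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    methods,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
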