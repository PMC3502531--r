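Package: ssmdscreen
Title: SSMD-Based Analysis of High-Throughput RNAi and Small-Molecule
    Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Plate-level quality control and hit selection for
    high-throughput RNAi and small-molecule screens run in 96- or
    384-well plates.  Computes per-plate control summaries and quality
    metrics (Z'-factor, method-of-moment SSMD, signal window) with
    iterative control-outlier knockout, scores wells by percent
    activity, z-score, robust z-score, SSMD, robust SSMD, the UMVUE of
    SSMD for replicated screens, or a paired t-test, classifies SSMD
    scores into the standard 21-bin effect-size scale, selects and
    annotates hits, and writes tab-delimited result tables, diagnostic
    figures and an HTML report.  Includes a synthetic screen generator
    with known ground truth for validation, and a protocol-file driven
    pipeline with extensive input validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
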