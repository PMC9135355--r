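Package: grnda
Title: Natural Decomposition of Bacterial Gene Regulatory Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decomposes signed directed gene regulatory networks into their
    system-level elements with the natural decomposition approach (NDA).
    Fits the power law relating mean clustering coefficient to
    out-connectivity by robust least squares, derives the kappa threshold
    that separates global regulators from local ones, partitions the
    remaining genes into locally independent modules, basal machinery, and
    intermodular genes, classifies each module as a concilion or a simple
    or complex regulon, and assembles the three-tier diamond functional
    architecture with its layer fractions. Includes a planted-structure
    synthetic network generator with ground-truth labels, incompleteness
    (edge/gene removal) simulation with per-class agreement reports,
    readers and writers for edge-list TSV, SIF, and Abasy Atlas exports,
    tidy/glance/autoplot methods for every result type, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    stringr,
    rlang,
    withr,
    igraph,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    MASS
Config/testthat/edition: 3
RoxygenNote: 7.3.3
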