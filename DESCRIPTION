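Package: fcss
Title: Flow Cytometric Seed Screen Analysis for Mixed-Ploidy Plants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for inferring reproductive pathways of seed formation
    (sexual reproduction, gametophytic apomixis and irregular pathways) from
    single-seed flow cytometry of embryo and endosperm nuclei, the flow
    cytometric seed screen (FCSS). Provides peak extraction from binned
    fluorescence histograms, reference-based DNA ploidy calling, peak-index
    classification of seed developmental pathways, decomposition of embryo and
    endosperm ploidies into female and male genomic contributions with
    maternal:paternal endosperm dosage ratios, a Monte Carlo permutation test
    for the within-plant association of reproductive modes, cytotype diversity
    and gene-flow screens, breeding-system statistics (seed set under selfing
    versus outcrossing, pollen/ovule ratios with Cruden-style classification)
    and pollen-viability comparisons among cytotypes. A generative simulator
    produces ground-truth-labelled studies of mixed-cytotype populations so
    that every stage of the pipeline can be validated without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    sandwich,
    stats,
    tibble,
    tidyr,
    utils,
    vegan,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
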