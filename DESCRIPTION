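Package: argthreader
Title: Demography-Aware Sampling of Ancestral Recombination Graphs and
    Introgression Mapping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Samples ancestral recombination graphs (ARGs) conditional on a
    user-defined demographic model with population splits, piecewise-constant
    sizes, and instantaneous migration bands. The core operation is a
    discrete-time coalescent "threading" hidden Markov model whose states are
    (branch, time, population path) triples, so that sampled local genealogies
    carry migrant lineages explicitly. Sampled ARGs are parsed into posterior
    probabilities of introgression along the genome, thresholded region calls
    with zygosity, and frequency-spectrum summaries used to date migration
    events. Includes a structured-coalescent simulator with ground-truth
    migrant tracts (driven by msprime) and basewise power/false-positive
    evaluation utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    IRanges,
    purrr,
    Rcpp,
    rlang,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    optparse
SystemRequirements: python3 with msprime and tskit (for the coalescent
    simulator module)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
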