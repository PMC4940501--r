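Package: rhizoweb
Title: Legume-Rhizobium Interaction Webs from 16S Nodule Surveys
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and analyses quantitative legume-rhizobium interaction
    webs from aligned 16S rRNA nodule sequences. Delineates bacterial taxa
    hierarchically (genotype and 99/98/95 percent identity clusters),
    constructs frequency-weighted bipartite plant-by-taxon webs per site,
    and computes network- and species-level descriptors (connectance,
    interaction evenness, weighted nestedness WNODF, Bluethgen H2' and d',
    generality, weighted bipartite modularity) with fixed-marginal null-model
    significance. Includes G-tests of clade-level nodule occupancy across an
    invasion gradient and a synthetic survey generator with planted taxon
    clusters and planted modular or nested web structure for end-to-end
    validation.
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
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    Biostrings,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
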