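Package: quantweb
Title: Quantitative Bipartite Host-Parasitoid Network Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Weighted metrics for quantitative bipartite host-parasitoid
    interaction webs (linkage density, weighted connectance, generality,
    vulnerability, the H2' network specialisation index with integer
    entropy bounds, and weighted bipartite modularity), together with the
    machinery needed to compare such webs across studies: interaction-event
    rarefaction and standardisation, host taxonomic diversity (Delta),
    a multi-study synthetic network generator, and the mixed-model
    residualisation workflow used to test latitude and host-guild effects
    on network structure.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    lme4,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
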