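Package: spermcomp
Title: Phylogenetic Comparative Analysis of Sperm Competition and Ejaculate Quality
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for relating sperm competition levels, proxied by relative
    testes mass, to sperm quantity and ejaculate quality traits across species
    while controlling for shared ancestry. Implements lambda-model phylogenetic
    generalized least squares with maximum-likelihood estimation of Pagel's
    lambda, sequential (Type I) sums of squares, effect sizes r with confidence
    limits, phylogenetically corrected pairwise correlations, single-linkage
    clustering of traits on a 1-r distance, and a principal-component "overall
    sperm quality" composite with varimax rotation. Ships a fixture dataset of
    species-mean traits for 18 muroid rodent species together with a consensus
    phylogeny, plus simulators for pure-birth trees and lambda-structured traits
    used for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    nortest,
    stats,
    utils
Suggests:
    nlme,
    jsonlite,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
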