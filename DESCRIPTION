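Package: psmsignal
Title: Phylogenetic Signal Screening for Binary Chemotaxonomic Traits
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measures phylogenetic signal in binary (presence/absence) traits on
    rooted phylogenies with the D statistic for discrete characters, using
    tip-shuffling and threshold-Brownian null distributions. Built for
    chemotaxonomic screens of plant secondary metabolite classes across a
    family-level seed-plant phylogeny: trait-matrix coding and summaries,
    family-level tree collapsing, clade-by-class signal screens, subsampling
    robustness experiments, trait lineages-through-time curves, and a
    synthetic-data generator (Yule trees plus four trait regimes with known
    signal) so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    Rcpp,
    jsonlite,
    stats,
    graphics,
    grDevices,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
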