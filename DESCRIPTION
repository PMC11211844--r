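Package: sdlineage
Title: Spatial Lineage Tracing by Joint Likelihood of CRISPR Barcodes
    and Cell Locations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Maximum-likelihood inference of spatial cell lineage trees
    from spatial lineage tracing data. Cell motility is modelled as a
    symmetric displacement of daughter cells at division followed by
    independent Brownian diffusion; CRISPR barcode evolution is modelled
    as an irreversible continuous-time Markov chain with heritable
    silencing and dropout. On a fixed tree topology the package
    co-estimates time-resolved branch lengths, the spatial diffusion
    rate, and the mutation-model parameters, under sequence-only,
    location-only, or joint modalities. Includes a forward simulator
    for topologies, locations, barcode matrices, and frame-by-frame
    tracks, plus evaluation utilities (branch-length MAPE,
    diffusion-rate bias, displacement-radius sweeps, and
    daughter-parent-daughter division-angle analysis).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    jsonlite,
    optparse,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    Matrix,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
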