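Package: cnvdist
Title: Copy-Number Analysis of DNA-Seq Data via Inter-Read Distances
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Detects DNA copy-number variation from whole-genome sequencing
    by modelling the base-pair distances between adjacent mapped reads
    instead of windowed read counts. Distances are artificially
    right-censored and modelled with finite mixtures of right-censored
    geometric distributions, optionally extended to a mixture of
    generalized linear models with a shared GC-content slope. Provides EM
    estimation with a Newton-Raphson M-step, a parametric-bootstrap
    likelihood-ratio test for the number of mixture components, a
    model-based inverse normal transformation of distances to z-values,
    recursive-combination change-point segmentation of binned z-values,
    and a simulation framework comparing distance-type with count-type
    read-depth analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, jsonlite, Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), Rsamtools, GenomicRanges, IRanges, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
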