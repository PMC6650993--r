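Package: alongtract
Title: Along-Tract Microstructure Profiling with Accumulator-Model
    Reaction-Time Decomposition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tractometry pipeline for studying brain-behaviour associations
    along white-matter tracts. Reduces 3-D tract probability volumes to smooth
    arc-length-parameterized curve skeletons by topology-preserving thinning,
    divides skeletons into overlapping equal-length segments, computes
    connection-probability-weighted microstructural metrics (NDI, ODI, FA, MD)
    per segment in native space, and tests segment-wise associations with
    behaviour using general linear models, one-dimensional threshold-free
    cluster enhancement and permutation familywise-error control. Includes a
    single-accumulator linear ballistic accumulator model of simple reaction
    time with quantile-based likelihood-ratio chi-square fitting to estimate
    non-decision time, frequentist and Bayesian Pearson correlation tests,
    repeated-measures ANOVA with Greenhouse-Geisser correction, and synthetic
    cohort generators that give every pipeline stage a known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    igraph,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    car,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
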