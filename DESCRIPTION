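Package: stratmatch
Title: Genetic Matching and Matched Trend Tests for Stratified Case-Control Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Controls population stratification in case-control association
    studies by genetic matching. Computes identity-by-state (IBS) similarity
    matrices from packed genotypes, builds optimal case-control pairs, groups
    and model-free clusters with a Hungarian assignment solver, validates
    matches by intra-cluster membership or a vicinity criterion, and tests
    association with matched extensions of the Cochran-Armitage trend test
    (linear and squared forms aggregated over matched units). Inference is by
    within-unit permutation with optional minP multiplicity adjustment,
    asymptotic reference distributions, and genomic-control rescaling.
    Includes a logistic-regression benchmark with multidimensional-scaling
    ancestry covariates, a Balding-Nichols simulator of stratified samples,
    and PLINK text PED/MAP input and output.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
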