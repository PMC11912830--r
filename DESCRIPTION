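Package: ibdtransect
Title: Effective Population Size Trajectories from Time-Transect IBD Sharing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates recent effective population size (Ne) trajectories from
    identity-by-descent (IBD) segments shared within and across sample sets
    collected at different time points, as is typical for ancient-DNA time
    transects. Implements coalescent expectations for IBD segment length
    densities between temporally offset haplotype pairs, a Poisson composite
    likelihood over binned segment counts, penalized maximum-likelihood
    inference of the Ne trajectory with chromosome-based cross-validation and
    bootstrap confidence intervals, a detection-error model (false positives,
    length-dependent recall, Gaussian length noise) with the matching rate
    correction, posterior distributions of segment TMRCA, and two simulators:
    a fast model-based Poisson sampler and an independent discrete-generation
    pairwise coalescent-with-recombination engine.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
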