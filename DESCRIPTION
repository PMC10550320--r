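Package: adaptarch
Title: Adaptive Architectures of Additive Quantitative Traits
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Forward simulators and analytical theory for the adaptive
    architecture of an additive quantitative trait under Gaussian stabilizing
    selection after a sudden shift of the trait optimum. Provides a
    Wright-Fisher simulator under linkage equilibrium, an individual-based
    simulator of haploid genomes on a linear chromosome, a multi-type Yule
    branching-process model of the establishment phase with its inverted
    Dirichlet limit, and the joint allele-frequency distribution conditioned
    on the population trait mean ("pheno-time" sampling), together with the
    size-ordered marginal distributions and summary statistics used to
    classify adaptive architectures from selective sweeps to subtle
    polygenic frequency shifts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
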