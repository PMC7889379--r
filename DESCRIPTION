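Package: famkat
Title: Kernel and Burden Association Tests for Multivariate Traits in
    Pedigree and Population Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Region-based association tests between multiple correlated
    phenotypes (continuous or binary) and sets of genetic variants in
    pedigree- or population-structured samples.  A joint generalized
    estimating equation (GEE) null model accommodates within-family and
    cross-trait correlation via a Kronecker working covariance; score-type
    statistics are then formed retrospectively, with the null variance
    derived from genotype moments (minor allele frequencies, genotype
    correlations, and kinship).  Provides a homogeneous kernel statistic,
    a heterogeneous kernel statistic, a weighted burden test, and Cauchy
    combination omnibus tests, with mixture chi-square p-values computed
    by a saddlepoint approximation.  Includes a simulation toolkit for
    two-subpopulation haplotype pools, nuclear-family gene drop, and
    correlated continuous or binary phenotypes, together with harnesses
    for empirical type I error and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    vcfR
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
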