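Package: ldner
Title: Linkage-Disequilibrium Estimation of Contemporary Effective
    Population Size and Its Robustness to Genomic Data Limitations
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Estimates contemporary effective population size (Ne) from
    linkage disequilibrium among unphased biallelic SNP genotypes, using
    the composite (Burrows-type) r-squared with the classical sample-size
    bias correction and delete-one jackknife confidence intervals, plus a
    Sved-equation distance-binned estimator of Ne in the recent past.
    Includes a forward Wright-Fisher simulator with recombination, two-deme
    migration and pedigree ancestry tracking; perturbation operators for
    missing data, SNP and individual downsampling, ancestry (Q-value)
    stratification and chromosome-map fragmentation; locus filters and the
    physical-linkage bias correction for chromosome number; a replicate
    experiment harness summarising estimates by geometric mean and
    percentile intervals; and PED/MAP and minimal VCF input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
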