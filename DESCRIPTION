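Package: gxescan
Title: Genome-Wide Gene-Environment Interaction Scans for Case-Control Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for genome-wide SNP-by-environment interaction studies
    (GWIS) of binary outcomes in stratified case-control cohorts.  Implements
    per-variant logistic interaction models with a robust (sandwich-variance)
    score test, genomic-control lambda estimation with F-test recalibration,
    allele-aligned fixed-effect inverse-variance meta-analysis across ancestry
    strata, statistical-stability screening of top hits, linkage-disequilibrium
    and CpG-site annotation helpers, and a synthetic two-ancestry cohort
    generator (Balding-Nichols allele-frequency divergence, block LD via a
    Gaussian copula, log-normal exposure, prevalence-calibrated logistic
    outcome) so the full pipeline can be exercised and validated without
    access-restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    metafor,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
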