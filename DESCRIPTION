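Package: snpdp
Title: Differentially Private Release of SNP Genotype Data by Top-Down
    Specialization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Disseminates case-control SNP genotype tables under
    epsilon-differential privacy. The genotype matrix is partitioned into
    contiguous SNP blocks, each block is generalized through a taxonomy
    (generalization) tree, a fixed number of randomly chosen specializations
    push the generalization cut downwards, and the counts of the resulting
    disjoint record partitions are released with Laplace noise. The package
    also ships the two standard evaluation instruments for such releases: a
    likelihood-ratio membership (re-identification) attack with power
    estimation at a fixed false-positive rate, and chi-square case-control
    association utility scored as significant-SNP recovery
    (accuracy/sensitivity/precision/F1), plus a synthetic cohort generator,
    an empirical differential-privacy audit, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    digest,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    vcfR,
    optparse
Config/testthat/edition: 3
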