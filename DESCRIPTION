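Package: minkr
Title: Minimally Invasive Karyotyping for Noninvasive Prenatal Aneuploidy Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detection of fetal chromosomal aneuploidy from shotgun sequencing
    of cell-free DNA in maternal plasma using the MINK (Minimally Invasive
    Karyotyping) algorithm. Aligned reads are counted into fixed-width genomic
    bins, corrected for library-specific GC bias by local (loess) regression,
    and each test library is compared against a panel of karyotypically normal
    reference libraries by regressing pairwise log2 count ratios on GC content
    over diploid chromosomes, predicting the target chromosome, and testing the
    prediction residuals with a one-sample t statistic; calls follow a
    median-p-value rule. Includes confusion metrics with exact binomial
    confidence intervals, the two-sample proportion test, read-depth titration
    by exact downsampling, a power calculation driven by fetal fraction, and a
    negative-binomial synthetic-cohort simulator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    Biostrings
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    Rsamtools,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
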