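Package: adipoChIP
Title: Poisson-Background ChIP-Seq Peak Calling and Colocalization
    Analysis for Histone Marks and Transcription Factors
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A tested, reusable implementation of a ChIP-seq analysis
    pipeline for histone-modification and transcription-factor binding
    profiles: strand-specific read extension and fixed-width genome
    binning, Poisson-background significance thresholding with an
    empirical IgG (mock IP) fold-enrichment filter, merging of
    significant bins into enriched regions, gene-level annotation by
    transcription-start-site windows, proximity and peak-set overlap
    statistics, binned-window colocalization correlation matrices, exact
    hypergeometric gene-category enrichment, and expression association
    tests. Includes a synthetic aligned-read simulator with planted
    enriched sites and a non-random shared background component, so the
    whole pipeline is testable end to end without external sequencing
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    Rsamtools,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: ChIPSeq, PeakDetection, Epigenetics, Coverage, Sequencing
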