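Package: repairkinetics
Title: Population-Scale DNA Repair Kinetics from Damage-Seq Time Courses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits the Kolmogorov-Johnson-Mehl-Avrami (KJMA) repair function
    f(t) = theta * (1 - exp(-(t/tau)^m)) to per-region DNA damage time
    courses (e.g. CPD-seq after UV irradiation), treating the sequencing
    signal as the superposition of independent cells. Provides the signal
    transformation from damage counts to repair fractions with
    dipyrimidine normalization and monotone rectification, segmentation of
    a genome into transcription-coupled-repair strata (transcribed and
    non-transcribed strand thirds, non-TCR blocks), prediction of ongoing
    repair rates for comparison with excision-repair (XR-seq style)
    signals via distance correlation, a k-nearest-neighbour
    shuffled-label significance procedure linking fitted parameters to
    genomic features, and a stochastic cells-by-positions simulator with
    Bernoulli repair competence and Weibull repair times that generates
    fully synthetic, parameter-recoverable data sets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    methods,
    GenomicRanges,
    IRanges,
    GenomeInfoDb,
    S4Vectors,
    Biostrings,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    class
Config/testthat/edition: 3
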