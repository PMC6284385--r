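Package: csffrag
Title: Fragment-Size and Copy-Number Analysis of Cell-Free DNA from
    Shallow Whole-Genome Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of cell-free DNA (cfDNA) from shallow whole-genome
    sequencing, aimed at cerebrospinal fluid (CSF) liquid biopsies. Implements
    fragment-length profiling, the 10 bp nucleosomal periodicity amplitude
    statistic computed from local extrema of the size distribution in the
    75-150 bp range, binned copy-number calling (GC/mappability correction,
    median-normalized log2 ratios, circular binary segmentation and Gaussian
    hidden Markov model segmentation with per-bin consensus), gene-level
    amplification/deletion calls, and cohort-level association between
    fragmentation amplitude and somatic copy-number alteration level. A
    synthetic cfDNA generator with tunable tumor fraction, nucleosomal size
    modes, periodicity amplitudes and copy-number events makes the full
    pipeline testable without access to patient sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    withr
Suggests:
    Rsamtools,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
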