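Package: plasmaCNV
Title: Copy-Number Analysis of Plasma Cell-Free DNA from Shallow
    Whole-Genome and LINE-1 Amplicon Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detection and quantification of somatic copy-number
    alterations in plasma cell-free DNA. Implements genome-wide
    aneuploidy z-scores from chromosome-arm LINE-1 read counts
    (mFAST-SeqS style), GC-corrected log2-ratio profiling from shallow
    whole-genome sequencing bin counts with change-point segmentation
    and focal-amplification calling (FGFR1 by default), tumor-fraction
    estimation by a grid-search fit of integer copy states with an
    absolute-copy-number back-calculation, FISH amplification scoring
    and tissue/plasma concordance, and tumor-fraction-based survival
    stratification. A synthetic cfDNA read-count generator with known
    tumor fraction and copy-number events provides ground truth for
    every stage.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    graphics,
    jsonlite,
    Rsamtools,
    stats,
    survival,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
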