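Package: promnuc
Title: Nucleosome Occupancy Inference on Promoters from Psoralen-Crosslink
    EM Traces, MNase Fragments, and Binding Titrations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Single-molecule analysis of psoralen-crosslink electron
    microscopy traces of reconstituted promoter DNA: paired strand polylines
    are calibrated to base-pair coordinates, inter-strand distance profiles
    are thresholded to segment single-stranded "bubbles", and bubbles longer
    than 90 bp are scored as nucleosomes. Per-condition nucleosome counts are
    summarised with Poisson fits, bootstrap confidence intervals, and an
    exact conditional Poisson rate test. Companion modules compute
    MNase-fragment occupancy tracks at 1 bp resolution, TSS-oriented
    occupancy matrices and aggregate profiles with fold-enrichment calls,
    and global single-site binding fits of fluorescence-polarization
    titrations. A synthetic-data generator plants known bubbles, positioned
    +1 nucleosomes, and binding curves so every stage is verifiable against
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    IRanges,
    S4Vectors,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2,
    knitr,
    rmarkdown
Config/testthat/edition: 3
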