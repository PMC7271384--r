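Package: nucpuncta
Title: Per-Nucleus Quantification of Punctate Nuclear Signal and
    Expression-Screen Filters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies punctate nuclear localization of a fluorescent
    marker on a per-cell basis from two-channel micrographs: nuclei are
    segmented from the DAPI channel, an adaptive per-nucleus intensity
    threshold (a multiple of the mean of the dim nuclear pixels) is
    applied to 3x3 neighborhood means of the marker channel, and the
    summed intensity of positive pixels is normalized by the mean
    nuclear intensity to give a scale-invariant localization score.
    Also provides tabular screening utilities (MA-plot preparation of
    FPKM tables with pseudocount and low-abundance discard,
    fold-change/significance gene selection, duplicate-spot antibody
    array fold-change hit calling), unpaired two-tailed t-test group
    comparison, and seeded synthetic-data generators (micrographs with
    known puncta ground truth, expression and spot tables) so every
    stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
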