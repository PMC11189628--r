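Package: mitoSpGFP
Title: Quantification of Mitochondrial Split-GFP Reporters, Flow Gating,
    and Genetic Screen Hit Calling
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing split-GFP complementation reporters of
    mitochondrial protein import in budding yeast. Implements per-cell
    quantification of mitochondrial reporter signal from multi-channel
    confocal z-stacks (sum projection, random-walker foreground
    segmentation, seeded watershed separation of adjoining cells,
    fraction-of-maximum mitochondrial masking, median reporter intensity),
    nucleocytoplasmic ratio measurement against a nuclear marker,
    flow-cytometry gate calibration and population statistics, and the
    fold-change and t-test rules used to call and classify hits in a
    genome-wide knockout screen. A seeded synthetic-data module generates
    microscopy fields, flow event tables and whole screens with full
    ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    EBImage,
    Matrix,
    yaml,
    jsonlite,
    tiff,
    tools
Suggests:
    testthat (>= 3.0.0)
biocViews: CellBiology, Software, Visualization, SingleCell
Config/testthat/edition: 3
RoxygenNote: 7.3.3
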