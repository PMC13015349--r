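Package: spfit
Title: Lineage-Barcode Fitness Inference and Stationary-Phase Performance
    Decomposition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for barcode lineage-tracking experiments in serial batch
    culture with variable-length stationary phase. Simulates barcoded yeast
    populations through growth cycles (phase-structured lineage fitness,
    bottleneck and sequencing noise, beneficial-mutation supply, dual-index
    hopping on a primer grid), counts barcodes from reads with UMI
    dereplication, estimates and corrects index hopping from deliberately
    empty index combinations, infers per-cycle lineage fitness relative to
    the population mean by a self-consistent estimator, decomposes fitness
    across transfer regimes into per-hour performance within growth-cycle
    intervals with error propagation, and quantifies early-versus-late
    stationary-phase trade-offs and mutation parallelism.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
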