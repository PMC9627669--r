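Package: rnaiscreen
Title: Analysis of Arrayed siRNA Reporter Screens with Plate-Wise Robust
    Z-Scores, Z'-Factor QC and Dual-Stimulus Counter-Screen Classification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for genome-wide arrayed RNAi reporter screens in
    384-well format: reading plate-matrix and long-table luminescence
    data, plate-wise robust Z-score normalization (median/MAD over sample
    wells), optional viability (TOX) normalization, per-plate Z'-factor
    quality control with replicate Spearman reproducibility, gene-level
    aggregation over multiple siRNAs with rank-based activator/suppressor
    hit calling and category exclusion, and classification of hits by a
    dual-stimulus counter screen into stimulus-selective groups. Includes
    a seeded synthetic-screen generator with known ground truth
    (multiplicative plate effects, log-normal well noise, per-siRNA
    knockdown efficacy) so the full pipeline is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
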