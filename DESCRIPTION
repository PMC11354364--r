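Package: WoundEntropy
Title: Entropy-Based Quantification of Scratch Wound-Healing Assays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantifies in vitro scratch (wound-healing) assays from
    phase-contrast micrographs by local Shannon entropy texture
    segmentation: the cell monolayer is texture-rich (high local entropy)
    while the cell-free wound is flat (low local entropy), so thresholding
    a disk-neighborhood entropy map separates wound from monolayer.
    Provides morphological cleanup, connected-component filtering,
    per-cell-line parameter presets, manual region overrides, and
    wound-closure kinetics expressed relative to the initial wound at T0.
    Also implements the companion microplate calculations of the assay
    workflow: MTT viability and growth-inhibition levels (GI50/GI25/GI10)
    by log-linear interpolation of dose-response curves, dual-dye
    fluorescence ratios (AO/PI, JC-1, NAO), and qPCR fold change by the
    delta-delta-Cq method. A synthetic-data module generates scratched
    monolayer images, closure time series, dose-response plates and Cq
    tables with exact ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports: methods, stats, utils, Rcpp, png, tiff
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), jsonlite, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
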