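Package: pdl1tps
Title: PD-L1 Tumour Proportion Score Assistance for IHC Image Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to assist scoring of PD-L1 immunohistochemistry (IHC) in
    non-small cell lung cancer. Provides a seeded synthetic generator for
    stained tissue patches with known ground truth, a trainable convolutional
    encoder-decoder for three-class tumour-cell segmentation (background,
    PD-L1 positive, PD-L1 negative), connected-component cell counting with a
    radius-4 merge, tiled region-of-interest tumour proportion score (TPS)
    computation, pixel-, object- and patient-level evaluation metrics, and a
    clinical interval router that flags scores near the 1% and 50% reporting
    cut-offs for mandatory pathologist review.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    EBImage,
    jsonlite,
    mgcv,
    png,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
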