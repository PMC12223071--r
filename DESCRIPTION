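Package: phantomfed
Title: Federated Brain-Tumor Image Analysis on Synthetic CT Phantoms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale, fully reproducible pipeline for privacy-preserving
    brain-tumor detection studies. Generates labeled CT-like brain phantoms
    with a pseudo cross-modality channel, preprocesses them (mutual-information
    rigid registration, morphological skull stripping, anisotropic diffusion,
    min-max normalization), segments tumors with a small residual/dense U-Net
    trained under Dice loss, extracts GLCM texture, first-order statistical
    and pooled deep features, selects features with a hybrid Gorilla-Badger
    metaheuristic wrapper, classifies with a capsule head using dynamic
    routing, and simulates federated averaging across heterogeneous clients
    with client dropout, model poisoning, differential-privacy noise, and a
    tamper-evident SHA-256 hash-chained ledger of per-round global models.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    EBImage,
    digest,
    jsonlite,
    png
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    RNifti,
    optparse
Config/testthat/edition: 3
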