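Package: pathproxy
Title: Cross-Modal Imaging-Pathology Alignment and Proxy-Based Survival
    Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Aligns volumetric brain-MRI representations and
    whole-slide-image (WSI) patch-feature sets in a shared unit-sphere
    embedding space with a symmetric, temperature-scaled InfoNCE
    contrastive objective. From the aligned model it builds a frozen
    cross-modal embedding library, retrieves proxy pathology embeddings
    for imaging-only patients by cosine nearest neighbour, and fuses
    imaging features with the proxy for binary 12-month overall-survival
    classification. Includes deterministic WSI preprocessing operators
    (tiling, Otsu background rejection, Macenko stain normalization,
    tumor-centroid volume cropping), a padding-aware multi-head attention
    patch aggregator with a CLS token, retrieval and classification
    metrics with analytic random baselines, and a synthetic paired-cohort
    generator for end-to-end evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    pracma,
    pROC,
    png,
    RNifti,
    optparse
Config/testthat/edition: 3
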