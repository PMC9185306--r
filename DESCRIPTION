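Package: endodiag
Title: Classical Image-Analysis Pipeline for Lower Gastrointestinal Endoscopy
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Image enhancement, region-based level-set lesion segmentation,
    handcrafted texture and colour descriptors (local binary patterns,
    grey-level co-occurrence statistics, fuzzy colour histograms), feature
    fusion with pluggable deep embeddings, shallow neural-network and support
    vector machine classifiers, and confusion-matrix/ROC evaluation for lower
    gastrointestinal endoscopy frames. Ships a deterministic generator of
    endoscopy-like phantom images with ground-truth lesion masks so the whole
    pipeline can be exercised end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    e1071,
    jsonlite,
    png,
    stats,
    utils,
    withr
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
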