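Package: pldetect
Title: Partial-Label Anchor Loss for Lesion Detection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for training anchor-based lesion detectors on partially
    annotated volumetric images. Implements dense anchor generation with
    IoU-based positive/negative label assignment, a negative-anchor masking
    scheme together with a lambda-weighted negative cross-entropy loss that
    reduces the penalty wrongly applied to unlabeled lesions, FROC evaluation
    (sensitivity at fixed false positives per image), a synthetic
    partially-annotated CT phantom generator, and a seeded experiment harness
    with a small trainable proposal scorer for ablation and parameter-sweep
    studies.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    RNifti,
    stats,
    utils,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
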