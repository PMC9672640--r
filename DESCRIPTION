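Package: dmilct
Title: Deep Multiple-Instance Learning for Treatment-Response Prediction
    from Volumetric CT
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Bag-level classification of volumetric CT with deep
    multiple-instance learning (MIL). A tumor cuboid resampled to 1 mm
    isotropic voxels and cropped to 64x64x32 is treated as a bag of 32
    axial-slice instances; a shared-weight convolutional backbone embeds
    each instance, and a MIL pooling head (max, convolutional, or
    attention-based) aggregates the instance embeddings into a single
    bag score. Includes stratified splitting, Adam training of the full
    backbone + pooling + classifier stack, a clinical evaluation suite
    (ROC/AUC with DeLong confidence intervals, Youden and
    minimum-distance cut-offs, decision-curve analysis), a seeded
    synthetic cohort generator at both the image and the embedding
    level, a minimal NIfTI-1 reader/writer, and a command-line
    interface. The convolutional machinery is implemented in base R, so
    the whole pipeline runs and is testable offline on a single CPU.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
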