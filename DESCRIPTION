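Package: handbaa
Title: Active-Learning Hand Segmentation and Bone Age Regression on Synthetic Hand Phantoms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale, fully automated bone age assessment pipeline:
    query-by-committee deep active learning for hand mask segmentation with a
    small U-Net, global-average-pooled deep features with 2-D PCA inspection,
    and kernel ridge / support vector regression ensembles mapping features to
    bone age in months. Ships a seeded synthetic hand-phantom generator
    (image, ground-truth mask, age, sex) emulating the intensity, contrast and
    brightness variance of paediatric hand radiograph collections, so the
    whole pipeline is runnable and testable without any clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    e1071,
    graphics,
    grDevices,
    jsonlite,
    kernlab,
    png,
    stats,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
LinkingTo:
    Rcpp
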