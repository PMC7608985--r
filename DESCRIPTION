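Package: cystquant
Title: Automated Recognition and Quantification of Cysts in Histological
    Images of Polycystic Kidney and Liver
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Headless pipeline for quantifying cystic disease severity from
    H&E-stained histological sections of polycystic kidney and liver.
    Recognizes cyst lumens by green-channel thresholding, k-means intensity
    refinement, morphological opening, border-following contour extraction
    and diameter filtering; discriminates true small cysts from tubule and
    duct false positives with a local-binary-pattern texture descriptor and
    a grid-searched RBF support vector machine; provides programmatic
    supervision edits (delete, add, complete, split, merge) with a
    replayable, undoable edit log; computes the cystic index, cyst counts,
    diameter profiles and severity classes; and scores detection
    sensitivity and specificity from the edit log. A seeded synthetic
    histology generator with exact ground truth supports end-to-end
    validation without real slide images.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    Rcpp,
    EBImage,
    e1071,
    xml2,
    png,
    tiff
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    jpeg
Config/testthat/edition: 3
RoxygenNote: 7.3.3
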