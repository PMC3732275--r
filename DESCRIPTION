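Package: liverseg
Title: Automatic Liver Segmentation of Volumetric MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for automatic segmentation of the liver in volumetric
    magnetic-resonance images. Implements the full processing chain: import of
    DICOM acquisition series with slice sorting and gap detection, per-slice
    preprocessing (sigmoid value-of-interest transformation, bias-field
    correction, average and Gaussian denoising, fixed-VOI contrast
    redistribution stored in named layers), three segmentation algorithms
    (seeded 3D region growing with 26-connectivity, adaptive slice-propagated
    thresholding driven by normalized cross-correlation, and greedy active
    contours driven by Gradient Vector Flow), morphological and
    cross-correlation postprocessing that removes leakage into neighbouring
    organs, slice-wise similarity validation against reference masks, and
    exhaustive grid-search parameter optimization. A deterministic phantom
    generator produces MRI-like abdominal volumes with ground truth so the
    whole pipeline can be exercised and benchmarked without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
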