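Package: fociQuant
Title: Counting Nuclear Foci in Two-Channel Fluorescence Microscopy Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Automated per-nucleus counting of nuclear foci (such as gammaH2AX
    foci marking DNA double-strand breaks) in two-channel fluorescence
    microscopy images. Nuclei are segmented from the DNA-stain channel by
    fuzzy-entropy (Huang) thresholding, morphological cleaning and
    distance-transform watershed; foci are detected in the foci channel by
    adaptive median filtering, white top-hat background correction, the
    H-maxima transform with an Otsu-derived height parameter, and regional
    maxima extraction. The package also provides a synthetic foci-image
    simulator with known ground truth, relative-difference reliability and
    blur-robustness benchmark protocols, and batch entry points that write
    CSV result tables and annotated overlay images.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    tools,
    EBImage,
    Rcpp,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
biocViews: CellBiology, Visualization, Software
RoxygenNote: 7.3.3
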