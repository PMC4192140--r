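Package: cartct
Title: Automated Morphometry of Contrast-Enhanced MicroCT Scans of Mouse
    Articular Cartilage
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Automated quantification of articular cartilage structure from
    contrast-enhanced microCT volumes of the mouse proximal tibia. Reads
    TIFF/NRRD/MHD volumes, re-slices them coronally, calibrates intensities
    to Hounsfield units, segments the stained cartilage layer by multilevel
    Otsu thresholding, places fixed-size regions of interest on the medial
    and lateral tibial condyles from the detected top edge and condylar
    symmetry axis, and computes voxel-count volumes, maximal-inscribed-sphere
    local thickness, planar thickness maps and profiles, signal-to-background
    contrast and stain-uptake time courses, and the paired statistics used to
    compare operated and control joints. A synthetic tibia phantom generator
    with analytic ground truth supports end-to-end validation without scan
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    tiff,
    jsonlite,
    EBImage
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
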