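Package: bunchpheno
Title: Berry-Level Phenotyping of Grape Cluster Images from Segmentation Masks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Post-processing and phenotyping toolkit for 2D grape-cluster
    images that have been segmented by an automatic instance-mask generator.
    Reads COCO run-length-encoded mask records, filters raw masks down to
    true berry masks (overlap-based merged-mask removal, relative geometric
    filters, iterative elliptical-Fourier + PCA outlier rejection), computes
    berry and cluster-architecture traits (ECDF position profiles, concave
    hulls, compactness, outline shape PCA), corrects visible-berry counts
    for occlusion with a cross-validated linear model, and estimates trait
    repeatability from replicated block designs. Includes a ground-truthed
    synthetic cluster simulator (3D berry packing, z-buffer occlusion
    rendering, distractor objects) so that every stage is testable without
    field images.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    grDevices,
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
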