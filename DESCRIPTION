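Package: hearttube
Title: Synthetic Zebrafish Heart-Tube Images and 3D Cardiac Morphometry
Version: 0.1.0
Authors@R: person("Repo", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools to quantify 3D fluorescence image stacks of the embryonic
    zebrafish heart tube: classical multiscale Laplacian-of-Gaussian nucleus
    detection with marker-controlled watershed instance segmentation and
    physical-unit volume measurement; assignment of nuclei to the five
    anatomical compartments (pre-atrium, atrium, atrioventricular canal,
    ventricle, postventricle); lumen morphometry (interface centroids, AVC
    length, central line, convolutedness/looping ratio); perpendicular
    membrane line-profile intensity quantification; group statistics
    (Mann-Whitney with exact small-sample permutation null, unpaired t,
    Kruskal-Wallis); and a synthetic heart-tube image generator with complete
    analytic ground truth so every stage is testable without acquired data.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    optparse,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
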