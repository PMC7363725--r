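Package: oralarea
Title: Intra-Oral Surface Area Quantification from CBCT-Like Volumes
Version: 0.1.0
Authors@R: person("ACTA", "Imaging", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantifies intra-oral surface areas (hard palate, tongue,
    dental hard tissue, remaining mucosa) from cone-beam computed
    tomography style voxel volumes. Provides Hounsfield-unit threshold
    segmentation with Gaussian smoothing and morphological closing,
    isosurface extraction to triangle meshes with STL input/output and
    flat hole filling, a landmark-driven geometric partition of the
    intra-oral surface into anatomical regions, craniofacial
    anthropometric distance measurement, and reliability statistics
    (two-way absolute-agreement average-measures intraclass correlation,
    Pearson correlation with significance, one-way ANOVA from raw or
    summary data). A synthetic phantom generator with analytic
    ground-truth areas makes the whole pipeline testable without scan
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
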