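Package: pianoSign
Title: Virtual Femoral Resection and Anterior Resection-Surface Morphometry
    for Mechanically Aligned Knee Arthroplasty
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates mechanically aligned total knee arthroplasty femoral
    resections on distal-femur triangle meshes and quantifies the shape of the
    anterior resection surface (the "grand piano sign"). Provides rotational
    reference axes (surgical transepicondylar axis, Whiteside's line,
    flexion-extension axis from sagittal circle fits, posterior condylar axis),
    mesh-plane sectioning, resection-profile peak and inflection morphometry
    (MedL/LatL, M'L'/ML, lateral deviation), a parametric implicit-surface
    generator of synthetic distal femurs with known ground truth, and the
    cohort statistics layer (Student t, chi-square, one-way ANOVA with
    Bonferroni pairwise ordering, ICC(2,1)) used to compare sexes and
    rotational references.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
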