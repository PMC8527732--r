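Package: octaphen
Title: Retinal OCT/OCTA Quantification and Phenotyping for Early Diabetic Retinopathy
Version: 0.1.0
Authors@R: person("Analysis", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantifies structural and microvascular biomarkers of early
    diabetic retinopathy from optical coherence tomography (OCT) B-scans and
    en-face OCT angiography (OCTA) images, and carries the derived eye-level
    measurements through a normative phenotyping and clustered regression
    analysis. Includes gradient-graph shortest-path segmentation of
    intraretinal layer boundaries with ETDRS-region thickness averages,
    bicubic-upsampled vessel-density and foveal avascular zone quantification
    in the 2.5-mm perifoveal annulus, classification of eyes into ischemia,
    neurodegeneration and subclinical-edema phenotypes against a control
    mean +/- 1.96 SD reference, and Gaussian generalized estimating equations
    with exchangeable working correlation for eye-within-patient clustering.
    Synthetic phantom generators for B-scans, angiograms and cohorts provide
    ground truth for every stage.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
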