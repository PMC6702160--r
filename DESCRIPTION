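Package: dcetrack
Title: Longitudinal Voxel-Wise DCE-MRI Response Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Voxel-wise analysis of paired dynamic contrast-enhanced MRI
    (DCE-MRI) visits for early prediction of treatment response in breast
    cancer. Provides a synthetic phantom and cohort generator with ground
    truth, MRI pre-processing (bias-field correction, histogram matching,
    resampling), a baseline deformable registration with attribute matching
    and mutual-saliency weighting, deformation-tensor feature maps (Jacobian,
    anisotropic deformation index, slab-rod index), three-timepoint kinetic
    features (peak enhancement, wash-in/wash-out slopes, signal enhancement
    ratio), Jacobian-scaled parametric response maps, per-tumor heterogeneity
    indices, and a cross-validated outcome-modeling protocol (logistic and
    Cox models, univariable ranking with nested best-subset selection by AIC,
    consensus refit with likelihood-ratio testing, and risk-signature
    survival stratification).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    survival,
    RNifti,
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
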