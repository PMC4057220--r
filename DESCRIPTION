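Package: lungqct
Title: Quantitative Thoracic CT Densitometry and Regional Lung Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Voxel-level gas/tissue decomposition of thoracic CT attenuation
    volumes, aeration-compartment classification, regional sterno-vertebral and
    apex-base profiling with superimposed hydrostatic pressure, normative
    reference equations for lung volumes and lung weight, and cohort-level
    statistics (Student's t comparisons, linear regression with confidence
    intervals, Bland-Altman agreement). Includes digital lung phantom and
    synthetic cohort generators with analytic ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
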