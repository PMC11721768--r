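Package: gmfmref
Title: Age-Conditional Reference Centiles for Gross Motor Function in
    Cerebral Palsy
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Builds motor development curves and age-conditional reference
    percentiles for interval-scaled gross motor scores (such as the GMFM-66)
    in children with cerebral palsy, stratified by GMFCS functional level.
    Implements the Box-Cox Cole-Green (LMS) distribution, penalized
    maximum-likelihood fitting of age-varying location, scale and shape
    curves by cubic smoothing splines with GAIC-guided smoothing selection,
    a repeated-measures adjustment that reports the median curve over
    one-observation-per-child subsample fits, bootstrap mean-difference
    bands for comparing reference curves across cohorts, and a synthetic
    registry-like cohort generator with known ground truth for validating
    every stage.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), withr, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
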