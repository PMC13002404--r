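Package: dtialps
Title: Simulation and Analysis Pipeline for the DTI-ALPS Glymphatic Index
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to simulate diffusion-weighted MRI phantoms with known
    periventricular fiber geometry, reconstruct voxelwise diffusion tensors
    by log-linear least squares, compute the DTI-ALPS (diffusion tensor
    image analysis along the perivascular space) index, and run the
    accompanying cohort statistics: two-group comparisons from raw data or
    published summary statistics, Mann-Whitney U with exact small-sample
    inference, chi-square tests, ROC analysis with DeLong variance and
    Youden-optimal cutoffs, logistic regression with univariate screening
    and backward elimination, and post-hoc power for the two-sample t-test.
    Includes a subject-level cohort simulator reproducing the marginal
    structure of a responder/non-responder epilepsy cohort.
License: MIT
Encoding: UTF-8
Imports:
    RNifti,
    jsonlite,
    stats,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
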