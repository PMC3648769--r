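Package: alemorph
Title: Coordinate-Based ALE Meta-Analysis and Voxelwise Gray-Matter
    Covariate Mapping
Version: 0.1.0
Authors@R:
    person("alemorph", "maintainers", email = "alemorph@localhost", role = c("aut", "cre"))
Description: A desk-scale pipeline for mask-restricted activation likelihood
    estimation (ALE) meta-analysis of reported activation coordinates with
    per-study kernel normalization and a permutation-derived critical score,
    and for voxel-based morphometry (VBM) style voxelwise correlation of
    gray-matter density with a behavioral covariate, thresholded by voxel
    p-value and cluster extent. Includes Talairach/MNI piecewise-affine
    coordinate conversion, a 25-item Likert empathy-scale scorer with cohort
    descriptives and a Kolmogorov-Smirnov normality check, minimal NIfTI-1
    volume I/O, a command-line driver, and seeded synthetic-data generators
    (foci tables, questionnaire cohorts, gray-matter image sets with an
    implanted covariate effect) for testing and calibration.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
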