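Package: craniomorph
Title: Geometric Morphometrics of Early Craniofacial Growth on Synthetic Skull Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A geometric-morphometrics toolkit for studying craniofacial
    ontogeny over the first 48 months of life, exercised end-to-end on a
    synthetic skull-cohort generator with known ground truth. Implements
    triangulated-mesh primitives with closed-volume and planar-circumference
    measurement, 3D thin-plate-spline warping and bending energy, surface
    semilandmark templating with bending-energy sliding, generalized
    Procrustes analysis with a flagged-landmark exclusion rule, craniometric
    dimensions, indices and cavity volumetry, and the statistical core:
    form-space principal component analysis, multivariate regression with
    permutation tests, ontogenetic trajectory angle comparisons and two-block
    partial least squares of shape against cavity-volume proportions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
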