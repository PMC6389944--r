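Package: penetract
Title: Penetrance-Weighted Tractometry of White-Matter Bundles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Streamline shape analysis and tractometry for cohorts of copy
    number variant (CNV) carriers, using CNV penetrance for schizophrenia and
    developmental delay as a continuous dose regressor. Provides tractogram
    (TRK/TCK) input/output, spline re-parameterisation of streamlines, a PCA
    shape basis with k-means clustering and bundle segmentation, bundle volume
    and median microstructure tractometry over NIfTI scalar maps, a built-in
    CNV penetrance lookup, general linear models with a covariate policy and
    max-statistic Freedman-Lane permutation correction, leave-one-CNV-out
    sensitivity analysis, global PCA of imaging variables, and a synthetic
    cohort generator that emulates the study design so the whole pipeline is
    testable without access to individual MRI data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    RNifti,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
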