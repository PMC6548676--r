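Package: cogsub
Title: Cognitively Defined Alzheimer's Disease Subgroups: Co-Calibration,
    Classification, and Subgroup Genetic Association
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for defining and genetically characterizing cognitively
    defined subgroups of late-onset Alzheimer's disease. Co-calibrates
    ordinal neuropsychological item data from multiple studies onto a common
    latent metric using anchored graded-response and bifactor item response
    models; classifies cases into six subgroups by substantial relative
    impairment of memory, executive functioning, language, or visuospatial
    functioning; runs case-subgroup versus shared-control SNP association
    scans with covariate adjustment, inverse-variance fixed-effect
    meta-analysis with Cochran's Q, and extreme odds-ratio suggestive-locus
    selection; and compares nested genetic risk-score models by likelihood
    ratio and paired DeLong AUC tests. Includes a synthetic multi-study data
    generator with planted subgroup structure so the full pipeline is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    metafor,
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
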