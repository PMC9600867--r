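Package: plaqueStretch
Title: Finite-Element Principal-Stretch Analysis of Calcified
    Atherosclerotic Plaque Cross-Sections
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Generates synthetic tissue-labeled cross-sections of
    atherosclerotic vessel walls (fibrous matrix, macro-calcification,
    lipid-rich necrotic core), inflates them to diastolic and systolic
    luminal pressure with a quasi-incompressible three-parameter Yeoh
    hyperelastic finite-element model on quadratic triangles, and
    quantifies how principal tissue stretch distributes around
    macro-calcifications: per-tissue stretch summaries, centerline
    stretch profiles, and near-versus-distant soft-tissue zone
    statistics relative to a reference stretch line.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    Matrix,
    Rcpp,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
NeedsCompilation: yes
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
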