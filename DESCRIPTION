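Package: connectotype
Title: Individual-Specific Functional Connectomes on Cortical Surface Meshes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for individual-specific functional connectome analysis on
    triangulated cortical surface meshes: synthetic cohort generation with
    planted functional topography and connection-encoded symptom scores,
    motion-based frame censoring with nuisance regression, spectral
    interpolation and band-pass filtering, atlas-guided iterative network
    parcellation with patch-to-ROI template matching, within- and
    between-network connectivity decomposition, inter-individual variability
    profiling, and genotype-stratified machine-learning prediction of clinical
    group membership and symptom severity with connection-level contribution
    analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    igraph,
    e1071,
    pROC,
    jsonlite,
    yaml,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
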