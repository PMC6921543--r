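Package: cytobool
Title: Boolean Network Inference from Temporal Cytokine Expression Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives Boolean-network models of macrophage activation from
    temporal cytokine panels. Implements penalized smoothing-spline profile
    enrichment, iterative L1 K-means binarization, sparse linear-programming
    structure inference, truth-table construction with two-level logic
    minimization, semi-tensor-product state-transition analysis (attractors,
    basins, evolution maps), and core-network reduction with trajectory
    reconstruction. Ships the published M1, M2a and M2c activation networks
    and their state-transition tables as fixtures, plus a synthetic-data
    generator that renders ground-truth Boolean dynamics through continuous
    shape kernels for end-to-end validation.
License: MIT + file LICENSE
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    boot,
    igraph,
    jsonlite
Encoding: UTF-8
Suggests:
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
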