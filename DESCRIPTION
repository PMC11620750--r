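Package: conceptflux
Title: Word-Level Naturalistic fMRI Analysis of Conceptual Processing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for word-level analysis of naturalistic (movie-watching) fMRI:
    amplitude-modulated deconvolution of impulse-response functions over a 20-second
    window with cardinal-spline or tent bases, voxelwise linear mixed-effects group
    inference with per-timepoint general linear tests, multi-threshold Monte-Carlo
    cluster-extent correction matched to residual smoothness, peaks-and-valleys
    reverse correlation of cluster-averaged BOLD against experiential norms with
    tie-corrected Kruskal-Wallis tests, and embedding-based contextual-situatedness
    scoring of words from object-label streams. Includes a synthetic-data generator
    that plants known ground truth in every input so the full pipeline can be
    exercised and validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tools,
    stats,
    utils,
    nlme,
    igraph,
    RNifti,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
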