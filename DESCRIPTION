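Package: l23continuum
Title: Archetypal Continuum Analysis of Cortical L2/3 Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to test whether a neuronal population forms a genuine
    transcriptomic continuum bounded by archetypes, to map that continuum onto
    curved cortical tissue coordinates, and to quantify how a perturbation
    redistributes cells along it. Implements principal convex hull (archetypal)
    analysis with a t-ratio permutation test, a within-type shuffling test that
    separates continua from noisy discrete types, diffusion pseudotime for cells
    and genes, curved pial coordinate fitting for imaging-based spatial
    transcriptomics, hybrid spatial-expression graph clustering, ABC archetype
    scores, optimal-transport redistribution maps, and pseudo-bulk differential
    expression. Ships generative simulators (latent 1-D expression continuum,
    discrete marker types with leaky expression, and a curved cortical section
    emulator) so the full pipeline runs and is tested without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Matrix,
    igraph,
    FNN,
    cluster,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    clue,
    optparse
Config/testthat/edition: 3
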