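Package: netanim
Title: Keyframe Animation of Styled Network Visualizations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A headless keyframe-animation engine for styled node-link network
    scenes. Scenes (nodes, edges, annotations and network-level visual
    properties) are captured as key frames on a seconds-denominated timeline,
    reconciled against the union object universe so objects added or removed
    between frames fade in and out, and tweened with a per-property
    interpolator taxonomy (linear colour and size interpolation, Bezier-eased
    alpha fades, categorical crossfades, visibility fades). Interpolated
    sequences are rasterized deterministically and exported as PNG frame
    sequences, animated GIFs, or MP4/H.264 movies. Includes JSON scene,
    storyboard and session formats, GraphML topology import, a seeded
    synthetic-fixture generator, and a command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    png,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
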