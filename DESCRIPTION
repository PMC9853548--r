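Package: mousetrackr
Title: Marker-Less Tracking and Social-Behavior Analysis of Multiple Mice
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tracking-by-detection for groups of unmarked mice filmed from above
    in an open-field arena. Per-frame animal contours come from a pluggable
    detector (a classical threshold segmenter is bundled; externally computed
    polygons can be loaded from VGG Image Annotator JSON). Identities are
    carried between frames by comparing correlogram appearance fingerprints --
    2-D histograms of pixel-pair distance and intensity sum -- with greedy
    ascending-dissimilarity assignment. Sporadic detection misses are filled
    automatically, candidate identity switches are flagged as tracking warnings
    for human review, and confirmed switches are repaired from swap directives.
    Social-behavior analytics (cumulative travel distance, inter-animal
    distance, proximity time) are computed from the corrected tracks. A
    seeded synthetic arena-video generator with full ground truth makes the
    whole pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    Rcpp,
    jsonlite,
    png,
    stats,
    tools,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
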