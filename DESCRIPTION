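Package: semanticnf
Title: Semantic Neurofeedback Engine for Real-Time fMRI Pattern Navigation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds representational semantic maps of mental states from
    multi-voxel fMRI activity patterns and drives closed-loop semantic
    neurofeedback. Implements pairwise pattern dissimilarity metrics
    (correlation distance, Euclidean, regularized Mahalanobis) and
    representational dissimilarity matrices (RDMs), classical
    multidimensional scaling with landmark-based out-of-sample projection of
    the current mental state, projection-based target-related pattern
    strength, the two feedback display geometries (semantic map with sized
    marker; circular thermometer arrangement with a similarity arrow), a
    deterministic closed-loop session driver with navigation performance
    metrics, and a synthetic simulator (anchor patterns with prescribed
    correlation structure, noisy trials, haemodynamically convolved volume
    streams, and a navigating participant agent) so the whole loop can be
    exercised without scanner data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    withr,
    RNifti,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
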