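Package: costruct
Title: Gesture-Vocal Co-Structuring Analysis of Segmented Melodic Motifs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies second-order co-structuring between voice and
    gesture in segmented vocal performances: motif pairs that sound alike
    are tested for co-occurring with gestures that move alike. Provides a
    dependent multidimensional dynamic time warping (DTW) distance with a
    Sakoe-Chiba band and fractional open endpoints, construction of
    all-pairs distance tables over four sonic features (f0, delta-f0,
    loudness, spectral centroid) and six kinematic features (hand/head
    position, velocity, acceleration), a Spearman correlation grid with a
    within-feature within-performer shuffle null and Bonferroni
    correction, gradient-boosted regression predicting sonic distances
    from kinematic distances under a repeated stratified cross-validation
    protocol, and a synthetic multimodal data generator with tunable
    gesture-vocal coupling for end-to-end validation.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    signal,
    xgboost,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
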