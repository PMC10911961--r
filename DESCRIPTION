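Package: ternHMM
Title: Hidden Markov Models for Visually Tracked Seabird Behaviour
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Fits two-state (foraging / not-foraging) hidden Markov models
    to 1 Hz GPS tracks of visually tracked seabirds, with gamma step-length
    and von Mises turning-angle state-dependent distributions, pooling and
    distance-to-colony covariate model variants, Viterbi and local (smoothed)
    decoding, and validation of decoded states against contemporaneous
    observer-recorded behaviours via confusion metrics (PPV, TPR, NPV, F1),
    logarithmic loss and foraging-event coverage. Includes reconstruction of
    the animal's track from observer position plus bearing and distance, a
    proxy-adequacy assessment of observer-platform tracks, and a synthetic
    data generator emulating two-state switching flight with a following
    boat.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    geosphere,
    optparse
Config/testthat/edition: 3
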