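Package: speckleapnea
Title: Non-Contact Apnea Screening from Laser Speckle Displacement
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end toolkit for detecting apnea-like breathing
    cessations from far-field laser speckle video. Provides a physics-based
    speckle simulator (rough-surface phase screen, Fraunhofer propagation,
    tilt-driven lateral shifts with programmable breath-hold episodes),
    frequency-domain frame-to-frame displacement tracking with parabolic
    sub-pixel peak interpolation, respiratory band isolation with a
    zero-phase Chebyshev Type I bandpass filter, normalized
    amplitude-threshold cessation detection with duration-based
    classification (normal, short, long), and nested five-fold
    cross-validated evaluation with inner-loop threshold selection.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    signal,
    stats,
    tiff,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
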