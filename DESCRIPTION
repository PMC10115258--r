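Package: fourhz
Title: Dissociating Hippocampal 4-Hz and Theta Oscillations During
    Stationary and Translational Running
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for separating the hippocampal 4-Hz (3-5 Hz)
    oscillation that emerges during stationary (wheel) running from the
    classical theta (6-10 Hz) rhythm of translational (maze) running, and
    for contrasting both before and after pharmacological inactivation of
    the medial septum.  Provides a synthetic-session generator with known
    ground truth (coupled oscillators over 1/f noise, Ornstein-Uhlenbeck
    running speed, phase-locked inhomogeneous-Poisson spike trains), LFP
    preprocessing (notch filtering, amplitude-based artifact rejection,
    speed gating), band decomposition with instantaneous Hilbert metrics,
    Welch spectral estimation with band power and interpolated peak
    frequency, autocorrelogram-based rhythmicity statistics for LFP and
    spike trains (min-max normalised autocorrelograms, band-window peak
    features, inclusion screening), binned Spearman correlation analyses,
    speed-matched trial subsetting, and a normality-gated two-sample
    testing convention.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
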