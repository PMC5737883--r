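Package: revphi
Title: Correlator Models and Analysis Tools for Reverse-Phi Motion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for studying the reverse-phi
    motion illusion in fly vision. Implements one-dimensional arrays of
    Hassenstein-Reichardt elementary motion detectors in two variants: the
    classical non-rectified four-quadrant correlator and a rectified
    two-quadrant correlator whose ON and OFF subunits admit a tonic (DC)
    luminance component before half-wave rectification. Provides generators
    for discretized phi, reverse-phi, and flicker/motion-decoupled grating
    stimuli as well as translating noise; spatiotemporal Fourier
    motion-energy analysis with quadrant quantification; velocity-tuning,
    time-constant, DC, and flicker-by-motion experiment batteries; and the
    trace-summarization procedures used for treadmill turning, tangential
    cell membrane potential, and calcium fluorescence recordings, together
    with seeded synthetic-data generators for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr,
    zoo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
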