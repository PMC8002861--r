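Package: flimphasor
Title: Phasor Analysis and Synthetic Scenes for Spectral FLIM of Membrane Probes
Version: 0.1.0
Authors@R: person("FLIM", "Phasor Maintainers", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for spectrally resolved fluorescence lifetime imaging (FLIM)
    of solvatochromic membrane probes: per-pixel phasor transform of TCSPC decay
    histograms, universal-circle geometry and phase/modulation lifetimes,
    phasor-driven segmentation of membrane phases, mono- and biexponential decay
    fitting with amplitude- and intensity-weighted mean lifetimes, brightest-
    percentile co-stain masks with lifetime-distribution and colocalization
    statistics, and a synthetic-scene generator with ground truth that
    reproduces the photophysics of locally excited, internal-charge-transfer and
    pH-activated emission states, including rising (excited-state reaction)
    decays that place phasors outside the universal semicircle.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    rhdf5,
    jsonlite,
    yaml,
    digest,
    stats,
    utils
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
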