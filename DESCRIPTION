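Package: teraspec
Title: Terahertz Time-Domain Spectroscopy Simulation and Optical-Constant Extraction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates terahertz time-domain spectroscopy (THz-TDS) measurements of
    small-molecule solids and aqueous solutions and extracts their optical constants.
    A seeded synthetic-data generator builds single-cycle reference pulses and
    propagates them through tablet slabs and microfluidic liquid cells described by
    Lorentz-oscillator dielectric models (with a double-Debye water background for
    solutions). The extraction chain implements the standard closed-form THz-TDS
    analysis: FFT, phase unwrapping with low-frequency anchoring, refractive index
    from the phase delay, and the Fresnel-corrected power absorption coefficient.
    Downstream tools detect absorption peaks, verify anomalous dispersion and
    Kramers-Kronig consistency, match peak lists across experiments with tolerance
    based pairing, and analyse concentration series measured in liquid cells.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    signal,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    pracma,
    optparse
Config/testthat/edition: 3
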