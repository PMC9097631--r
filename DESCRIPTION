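Package: hemeEPR
Title: Crystal-Field and Pulse EPR Analysis of Low-Spin Ferric Heme Proteins
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis toolkit for continuous-wave and pulse EPR spectroscopy
    of low-spin ferric (S=1/2, d5) heme centres such as cytochrome P450.
    Implements the Griffith-Taylor one-hole crystal-field analysis connecting
    principal g-values to t2g orbital mixing coefficients and the rhombic and
    axial crystal-field parameters; a field-swept powder spectrum simulator
    with anisotropic Gaussian g-strain; least-squares recovery of g-tensor and
    broadening parameters from experimental spectra; proton HYSCORE nuclear
    frequency and correlation-ridge analysis with point-dipole electron-proton
    distance estimation; the 2D time-to-frequency HYSCORE processing chain
    (polynomial baseline, Hamming apodization, zero filling, 2D Fourier
    transform, magnitude); a reader/writer for the Bruker BES3T file format;
    and a seeded synthetic-data generator for all of the above.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    signal,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
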