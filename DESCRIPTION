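Package: dsoptode
Title: Optode-Position Error Propagation in Self-Calibrating and
    Dual-Slope Frequency-Domain NIRS
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulation framework for quantifying how errors in optode
    (source and detector) positions propagate through self-calibrating (SC)
    and dual-slope (DS) frequency-domain near-infrared spectroscopy
    measurements of absolute tissue optical properties (absorption and
    reduced scattering coefficients) and of absorption changes. Implements
    the semi-infinite homogeneous photon-diffusion forward model with an
    extrapolated boundary, the SC slopes and iterative inversions for
    absolute optical properties, DS intensity and phase recovery of
    absorption changes via complex mean pathlengths, and the error-analysis
    machinery: displacement error maps, circle-orbit RMS error metrics for
    single and co-varied optodes, zero-change iso-lines, and probe support
    directions, for linear, asymmetric-linear, trapezoidal, and
    diagonal-rectangular optode arrangements.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    pracma,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
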