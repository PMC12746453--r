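Package: eoexcite
Title: Electron-Only Explicit Excitation Scheme for Surface-Hopping Initial
    Conditions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Generates initial electronic states and start times for trajectory
    surface hopping by explicitly propagating the electronic Schroedinger
    equation under a laser pulse with frozen nuclei (the electron-only explicit,
    "EOE", scheme), followed by renormalized stochastic selection via global
    flux surface hopping probabilities. Bundles a full validation stack for
    one-dimensional two-state systems: an analytic NaI diabatic model and
    harmonic fixtures, Gaussian laser pulses with spectral diagnostics, Wigner
    phase-space sampling of the vibrational ground state, grid-based quantum
    dynamics (imaginary-time ground state, split-operator propagation with
    dipole coupling), field-free 1D surface hopping with local diabatization
    and energy-based decoherence, and the closed-form coherently driven
    two-level model used as an analytic oracle.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    ggplot2,
    rlang,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    pracma,
    deSolve
Config/testthat/edition: 3
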