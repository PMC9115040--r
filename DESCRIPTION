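Package: elfxs
Title: Energy-Loss Functions and Inelastic Electron Cross Sections from
    Linear-Response Dielectric Theory
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes the energy loss function (ELF) of periodic model
    systems from the random-phase-approximation (RPA) Dyson equation for
    the density-density response, with and without crystal local-field
    effects, and turns tabulated ELF surfaces into the quantities used by
    Monte Carlo track-structure codes: double- and single-differential
    inelastic scattering cross sections, total inelastic cross section,
    inelastic mean free path and electronic stopping power in the
    plane-wave Born approximation.  The total ELF can be decomposed into
    electron-hole pair, occupied-energy (DELF), species, angular-momentum
    and molecular-orbital channel contributions.  Ships toy Kohn-Sham
    model generators (homogeneous electron gas, a gapped four-band
    water-like system), parametric Drude ELF surfaces, and the analytic
    complex Lindhard response as an oracle.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    withr,
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
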