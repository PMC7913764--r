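Package: aerodpi
Title: Aerodynamic and Physicochemical Characterization of Dry Powder Inhalers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Data reduction and simulation tools for carrier-free dry powder
    inhaler (DPI) development: particle-size-distribution statistics from
    laser-diffraction quantiles (Span, Sauter-mean specific surface area),
    bulk/tapped density flowability indices (Hausner ratio, Carr index),
    solid surface free energy from two-liquid contact angles via the Wu
    harmonic-mean equations, crystallinity indices from X-ray powder
    diffractograms, dissolution profiles with sampling-withdrawal correction,
    diffusion-cell flux and permeability coefficients, Andersen cascade
    impactor reduction (emitted and fine-particle dose, MMAD and GSD by
    log-probability regression), and a stochastic Monte Carlo simulator of
    regional lung deposition in a randomized asymmetric airway tree.
    Includes synthetic-data generators for every reduction so the whole
    pipeline is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    pracma,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
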