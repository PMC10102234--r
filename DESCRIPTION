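Package: psmsim
Title: Delay-Differential-Equation Model of the Zebrafish Segmentation
    Clock and the Ripply/Tbx6 Bistable Switch
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a gene regulatory network for zebrafish
    somitogenesis on a moving one-dimensional array of presomitic
    mesoderm cells: a delayed Her negative-feedback oscillator, Ripply
    induction gated by the clock and by an Erk activity gradient, and a
    bistable Tbx6 switch whose saddle-node bifurcation converts the
    travelling clock wave into a static segmental pattern. Provides an
    explicit-Euler integrator for the delay differential equations with
    exact grid advection, steady-state and bifurcation analysis of the
    Tbx6 switch (production/degradation curves, saddle-node thresholds,
    boundary-formation phase diagrams), mutant scenarios (her and ripply
    knockouts, MEK inhibition, loss of Tbx6 autoregulation, stepwise
    Erk-border shifts), and detectors that quantify the simulated
    spatio-temporal patterns (Tbx6 boundary events, somite spacing,
    kymographs, oscillation period profiles, wave-arrest positions and
    expression-domain extents), together with ground-truth synthetic
    pattern generators used to validate the detectors.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    graphics,
    grDevices,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
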