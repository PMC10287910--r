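Package: para2kin
Title: Kinetic Simulation and Inference for the ParA2 ATPase Cycle
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Forward simulation and kinetic inference for the ATPase cycle of
    the Vibrio cholerae chromosome 2 partition ATPase ParA2. Provides a
    mass-action reaction scheme of the cycle (ATP binding, slow conformational
    remodeling to the DNA-binding-competent state, cooperative loading on
    nonspecific DNA, hydrolysis-coupled release, ADP release and nucleotide
    exchange), deterministic ODE and exact stochastic simulation engines,
    synthetic-data generators for the standard in vitro assays (stopped-flow
    MANT-nucleotide kinetics, tryptophan-fluorescence conformational switch,
    EMSA titrations, DNA-carpet TIRF time courses, FRAP recovery, radiolabel
    ATPase time courses and CD thermal melts), the matching fitting procedures
    (single- and double-exponential, pseudo-first-order, Hill, hyperbolic,
    Boltzmann melt, FRAP and a staged global cycle recovery), and a 1D
    reaction-diffusion simulator of pole-to-pole ParA2 oscillations driven by
    a localized ParB2-parS2 hydrolysis focus.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    deSolve,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
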