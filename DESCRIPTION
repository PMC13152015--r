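Package: ctgain
Title: Corticothalamic Mean-Field Gain Estimation from Postictal EEG Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Minute-by-minute estimation of cortical, corticothalamic and
    intrathalamic synaptic gain parameters from EEG power spectra using the
    Robinson four-population corticothalamic mean-field model. Provides the
    closed-form linearized model spectrum, a Metropolis-Hastings sampler that
    inverts it per minute-wise channel-median Welch PSD, saturating-exponential
    and sigmoid trajectory fits with AIC selection, extraction of gain-regime
    values at clinically meaningful time points (first postictal minute,
    reorientation time, one hour), a stochastic time-domain simulator of the
    full delay-differential system, and a synthetic postictal cohort generator
    used for validation and as the spectral oracle. Reads EDF recordings and
    delimited spectral tables; a command-line entry point ties the stages into
    a reproducible pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    minpack.lm,
    signal,
    stats,
    tools,
    utils,
    graphics,
    grDevices,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
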