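Package: nfwaves
Title: Propagating Wave Dynamics in a Two-Dimensional Refractory Neural Field
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and semi-analytic analysis of a two-variable neural
    field model with refractoriness on a periodic two-dimensional domain.
    Provides the Bessel-based Mexican-hat coupling kernel and its integrated
    excitation/inhibition coordinates, bump and traveling-wave solutions,
    direct numerical integration with multiplicative noise, center-of-mass
    wave tracking and regime classification, and time-series statistics
    (spectral degrees of freedom, approximate entropy, detrended fluctuation
    analysis) together with spatiotemporal velocity-power spectra for
    characterizing collective wave dynamics as excitation and inhibition are
    varied.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    igraph,
    lhs,
    pracma
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
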