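Package: chemnoise
Title: Signal and Noise Propagation in the E. coli Chemotaxis Pathway
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Langevin model of the Escherichia coli chemotaxis signalling
    pathway from chemoreceptor complexes to the flagellar rotary motor.
    Provides MWC receptor-complex activity and adapted-state solvers, the
    full phosphorylation cascade (CheA, CheY, CheB) with receptor
    methylation adaptation, an MWC model of motor switching, deterministic
    Euler and stochastic Euler-Maruyama integrators with correlated
    shared-noise routing, analytic frequency-domain response functions and
    source-decomposed noise power spectra via a linear-noise matrix engine,
    power-spectral-density estimation from time series, and integrated
    signal response, band-limited variance and signal-to-noise analyses
    over receptor complex size and adaptation rates, including
    fluctuation-response relationships.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
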