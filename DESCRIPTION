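Package: phagenet
Title: Inference of Quantitative Phage-Bacteria Infection Networks from
    Community Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to infer who-infects-whom in virus-bacteria communities
    from density time series. Simulates multi-host, multi-virus generalized
    Lotka-Volterra dynamics, generates ensembles of binary infection matrices
    spanning a spectrum of nestedness (NODF), derives feasible parameter sets
    from target coexistence equilibria, and reconstructs the quantitative
    infection network (effective adsorption-times-burst rates) together with
    viral decay rates by non-negative least squares on discrete
    log-derivatives of the virus trajectories. Includes the in silico
    evaluation protocols: perturbation-size sweeps, multi-experiment designs
    at a fixed measurement budget, sampling-interval by horizon design
    surfaces, and measurement-noise robustness.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    pracma,
    vegan,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
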