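Package: saccstd
Title: Microsaccade-Evoked V1 Responses from Short-Term Depression in a
    Feedforward LGN-V1 Spiking Network
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis of a feedforward thalamocortical
    spiking model of visual fading and microsaccade-related neural
    responses. LGN relay neurons with Gaussian receptive-field tuning emit
    Poisson spike trains that drive conductance-based integrate-and-fire V1
    neurons through synapses subject to short-term depression
    (multiplicative depletion with exponential recovery). Includes exact
    event-driven depression kinetics and their analytic steady states,
    stimulus and microsaccade protocol builders (stationary, flashing,
    single, periodic and Poisson saccade trains, finite-velocity
    trajectories), a fast compiled time-stepped simulator, moving-bin
    response analyses, and the parameter-sweep experiments that
    characterise fading time, frequency sensitivity, flashing-versus-
    stationary differences, and response saturation with microsaccade
    magnitude and velocity.
License: MIT + file LICENSE
Encoding: UTF-8
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
Config/testthat/edition: 3
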