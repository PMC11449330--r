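Package: somnet
Title: Three-Population Integrate-and-Fire Simulation of Sleep-Wake Bout
    Dynamics
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates a stochastic sleep-wake switch built from three
    all-to-all coupled populations of leaky integrate-and-fire neurons:
    a wake-active population, a sleep-active population, and a
    wake-promoting (locus coeruleus) population. Mutual inhibition
    between the wake- and sleep-active populations creates a bistable
    switch; independent per-neuron Poisson drive triggers state
    transitions. Parameter presets emulate developmental stages by
    strengthening locus-coeruleus connectivity. Includes sliding-window
    behavioural state classification, bout extraction and statistics,
    survivor-curve construction, and exponential versus power-law-like
    distribution-shape diagnostics of bout durations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0)
LinkingTo: Rcpp
Config/testthat/edition: 3
NeedsCompilation: yes
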