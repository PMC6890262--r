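Package: onoffcoding
Title: Efficient Coding of Sensory Stimuli by ON/OFF Populations of Poisson Neurons
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying efficient population coding by binary-rate
    Poisson neurons of ON and OFF type. Computes exact and closed-form mutual
    information between a one-dimensional stimulus and population spike
    responses, allocates firing thresholds optimally under two criteria
    (information maximization and minimal mean squared error of the optimal
    linear readout), accounts for spike costs, validates results by Monte
    Carlo simulation of Poisson spiking, and reverse-infers stimulus
    distributions from measured threshold distributions such as olfactory
    receptor neuron activation thresholds.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    utils,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
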