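Package: apicobasal
Title: Apical and Basal Dendritic Contributions to Orientation Tuning in a
    Model Pyramidal Neuron
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A multicompartment conductance-based simulation of a layer 2/3
    visual-cortex pyramidal neuron, together with the in-silico protocol
    suite used to dissect how the apical and basal dendritic trees shape
    somatic orientation tuning. Provides SWC morphology handling and
    morphometrics, region- and distance-dependent channel density rules,
    orientation-tuned Poisson synaptic drive, an implicit branched-cable
    integrator with just-in-time ionic and synaptic interventions,
    per-spike attribution (apically driven, basally driven, cooperative),
    dendritic nonlinearity profiling (paired-pulse input-output curves and
    the NRLE index), EPSP and spike attenuation probes, and tuning
    statistics (OSI, tuning width, preferred orientation, linear
    Euler-formula expectation under dendritic disparity).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
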