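Package: trnlab
Title: Biophysical Models of Thalamic Reticular Neurons and Spindle Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Conductance-based compartmental modelling of thalamic reticular
    nucleus (TRN) neurons and their contribution to sleep-spindle oscillations.
    Provides simplified soma-plus-basal-dendrite morphologies with SWC
    round-trip, Destexhe-family membrane mechanisms (fast Na/K, generic T-type
    calcium with a dendritic density gradient and window-current voltage shift,
    SK-type calcium-activated potassium, calcium-activated cation, A-type
    potassium, first-order calcium dynamics), an implicit cable-equation
    integrator with rebound-burst and tonic current-clamp protocols,
    burst-oriented electrical feature extraction (burst number, runaway drift
    metric, post-burst tonic count), skewed-Gaussian burst-curve fitting,
    Markov chain Monte Carlo sampling of model populations against feature
    Z-score costs, and a reduced thalamoreticular network with Tsodyks-Markram
    synapses and gap junctions for peri-event spindle analyses (mean peak
    firing, corticothalamic sigmoid turning points, effective T-type
    conductance prediction). Synthetic trace and cohort generators with known
    ground truth support fully offline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    minpack.lm,
    optparse,
    withr
Config/testthat/edition: 3
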