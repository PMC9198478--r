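Package: satif
Title: Saturating Integrate-and-Fire Neurons and Linearly Non-Separable
    Boolean Computations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates single-compartment leaky integrate-and-fire neurons
    whose synaptic inputs are pooled into independently saturating
    conductance groups (the saturating integrate-and-fire, SIF). Provides
    constructors and certifiers for partial Boolean truth tables --
    including the compact feature binding problem family and XOR -- with
    linear-programming and exhaustive-search linear-separability
    certificates, a pairing-based non-separability proof checker, and a
    stimulation-episode protocol (single-spike or Poisson rate coding) that
    calibrates a neuron model and decides whether it implements a given
    truth table. Includes delimited-text readers and writers for spike
    trains and truth tables, a YAML configuration format, and a command
    line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    boot,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
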