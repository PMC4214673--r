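Package: glomsim
Title: Spiking-Network Model of Odor Information Segregation in the
    Olfactory Bulb Glomerular Layer
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates the glomerular layer of the olfactory bulb as a
    network of Izhikevich spiking neurons (mitral, external tufted,
    periglomerular and short axon cells) wired into inter-connected
    glomerular microcircuits, and runs in-silico odor experiments in
    which mitral-cell output encodes odor identity while external
    tufted-cell output encodes odor concentration.  Provides a seeded
    synthetic odor-stimulus generator (combinatorial receptor code,
    concentration series and binary-mixture morphing), fixed-step
    Runge-Kutta integration of heterogeneous neuron populations,
    current-based exponential synapses, and analysis metrics: Fisher's
    discriminant ratio, Pearson correlation with stimulus
    concentration, principal component analysis and divisive
    (bisecting) k-means hierarchical clustering with Newick export.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    ape,
    jsonlite,
    optparse
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
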