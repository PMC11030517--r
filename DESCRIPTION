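Package: frustranet
Title: Dynamic Frustration in Gap-Junction-Coupled Excitable Neuron Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates quadratic integrate-and-fire neurons near the
    saddle-node homoclinic orbit bifurcation, coupled diffusively (gap
    junctions) on square and triangular lattices and entrained by a periodic
    external drive. Provides the synchrony statistics used for calcium-imaging
    trace analysis (windowed deviation score, neighbour cross-correlation,
    sync fraction, spike-phase offsets, power-law scaling fits), a synthetic
    calcium-trace generator with Poisson-distributed stimulus-onset delays,
    and configuration-driven experiments reproducing the period-sweep,
    coupling-sweep, and lattice connectivity/disruption results.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
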