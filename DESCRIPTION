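Package: mepdkndy
Title: Coupled Amygdala GABA-Glutamate and KNDy Pulse-Generator Dynamics
Version: 0.1.0
Authors@R:
    person("MePD-KNDy", "Maintainers", email = "maintainers@mepdkndy.org",
           role = c("aut", "cre"))
Description: Simulation and numerical bifurcation analysis of a Wilson-Cowan
    mean-field model of the GABA-glutamate circuit in the posterodorsal medial
    amygdala (MePD), one-way coupled to a coarse-grained model of the arcuate
    KNDy network (the GnRH pulse generator). Provides adaptive Runge-Kutta
    integration with dense output, pseudo-arclength continuation of equilibria
    with Hopf and saddle-node detection, limit-cycle continuation by single
    shooting, two-parameter bifurcation loci with Bogdanov-Takens and cusp
    points, a period-blow-up homoclinic approximation, torus-bifurcation
    location for the coupled system, pulse/inter-pulse-interval statistics, and
    scenario drivers for kisspeptin stimulation, receptor antagonism and
    projection-stimulation in-silico experiments.
License: MIT + file LICENSE
Encoding: UTF-8
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
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
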