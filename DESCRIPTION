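Package: zymoflux
Title: Kinetic, Thermodynamic and Dynamic Flux Balance Modeling of
    Glucose/Xylose Co-Utilization for 2,3-Butanediol Production
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the co-fermentation of glucose and xylose by an engineered
    2,3-butanediol-producing Zymomonas mobilis strain at three levels. (1)
    Transporter-level Michaelis-Menten uptake kinetics with mutual competitive
    inhibition, forward ODE simulation against an interpolated biomass curve
    and multi-restart least-squares parameter estimation. (2) Pathway-level
    thermodynamics: max-min driving force (MDF) optimization by linear
    programming over log metabolite concentrations, cumulative Gibbs free
    energy profiles, thermodynamic bottleneck detection, and minimal enzyme
    protein cost per unit pathway flux under a common modular rate law with
    Haldane-consistent reverse rates. (3) A core-network dynamic flux balance
    simulator (static optimization approach with lexicographic objectives)
    used to scan initial sugar ratios and oxygen transfer (kLa) conditions
    for 2,3-butanediol productivity and titer. A synthetic-data module
    generates batch fermentation time courses and toy pathways with known
    ground truth for testing every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    minpack.lm,
    nloptr,
    quadprog,
    stats,
    utils,
    xml2
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
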