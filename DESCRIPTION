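Package: crossbridge
Title: Mechanokinetic Modelling of the Actomyosin Cross-Bridge Cycle
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis of the force-generating actomyosin
    cross-bridge cycle of fast skeletal muscle myosin II, extended with a
    stereospecific pre-power-stroke state (AM*'DP) and a phosphate-release
    state (AM*DP), plus blebbistatin-bound copies of the cycle states.
    Provides strain-dependent transition rates closed by detailed balance
    against parabolic free-energy profiles, a steady-state solver for
    solution (actin-activated ATPase) kinetics with Michaelis-Menten fits,
    an event-driven Gillespie simulator of motor ensembles propelling a
    rigid actin filament (in vitro motility and half-sarcomere protocols,
    including stretch ramps with critical-force extraction), generators of
    pseudo-experimental data sets, and a sum-of-squared-errors comparison
    of competing hypotheses for the mechanism of blebbistatin action.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    knitr,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
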