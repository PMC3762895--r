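Package: rrsim
Title: Deterministic Simulation of Reduce-and-Replace Transgenic Mosquito Releases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genotype-structured ordinary differential equation model of an
    Aedes aegypti population subject to continuous releases of transgenic
    mosquitoes carrying female-killing (FK) and/or anti-pathogen (AP)
    transgenes. Implements the two-locus Mendelian inheritance tensor, the
    closed-form wild-type equilibrium, density-dependent juvenile mortality,
    piecewise-constant release forcing, wild-type immigration, a catalogue of
    release-scenario designs (ratio-duration sweeps at fixed budget, single-sex
    and bi-sex releases, fitness-cost and immigration variants), and derived
    outcome metrics such as competent-vector density at population recovery,
    minimum native female density, and allele extinction times. Results are
    returned as tidy tibbles with ggplot2 plotting methods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
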