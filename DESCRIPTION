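Package: gelswell
Title: Dynamic Swelling of a Two-Phase Polyelectrolyte Gel Model of Gastric Mucus
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Simulates the dynamic swelling of a polyelectrolyte gel, such as
    gastric mucus, using a two-phase (network/solvent) mixture model in one
    spatial dimension. Dissolved sodium, calcium and chloride move by
    electrodiffusion through the solvent under an electroneutrality closure;
    cations bind and unbind to negative network sites by mass-action kinetics,
    with divalent calcium able to bind twice and form transient crosslinks.
    The crosslink fraction feeds back on the gel energetics through a
    crosslink-dependent Flory-Huggins-type interaction parameter, and
    gradients of the resulting chemical potentials drive quasi-static
    network and solvent motion. Includes the well-mixed equilibrium solver
    used to construct initial conditions, a stiff-kinetics integrator,
    swelling-front tracking, exponential swelling-rate fitting, and
    bath-molarity sweep utilities, with tidy tibble outputs and ggplot2
    autoplot methods throughout.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    Matrix,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
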