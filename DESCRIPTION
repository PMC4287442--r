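Package: polymersim
Title: Multi-Scale Polymerization Simulator Fusing L-Systems, Agents and
    Density Steering
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Headless, scriptable simulator of polymer growth that fuses
    three models operating at different time scales: a parametric open
    L-system with communication symbols describes the large-scale growth
    grammar of the polymer, an agent-based system moves individual
    monomers by Brownian dynamics and binds them at active sites, and a
    system of densities reconciles the agent population against
    user-steerable per-type concentration schedules.  A line-oriented
    rule DSL encodes alphabets, axioms and stochastic conditional
    production rules; a quaternion turtle interprets derived strings into
    placed 3-D geometry.  Ships four scenario bundles (cellulose,
    poly-ADP-ribose, microtubule, a synthetic branching showcase),
    branching-uncertainty annotation, CSV/OBJ structure export and a
    command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
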