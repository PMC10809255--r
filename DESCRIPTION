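Package: dyetraj
Title: Adsorption States, Dimer Kinetics and Pulling Energetics of Dyes on
    Silica Nanoparticles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Post-processing toolkit for molecular-dynamics trajectories of
    cationic xanthene dyes (rhodamine 6G) interacting with charged silica
    nanoparticles. Segments per-dye surface-distance and orientation time
    series into trapped, reorienting and stably adsorbed episodes, detects
    pi-stacked dimers and transient trimers with their lifetimes and end
    reasons, estimates binding energies from constant-velocity steered-MD
    force traces via the spring potential-energy release across unbinding
    transitions, and performs nanoparticle surface bookkeeping (silanol and
    counterion densities, pH ionization, neutralization and atom counts).
    Includes a rigid-body Brownian-dynamics generator of synthetic
    trajectories and sawtooth force traces with known ground truth, so the
    full pipeline is testable without an MD engine.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    data.table,
    jsonlite,
    yaml,
    bio3d
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
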