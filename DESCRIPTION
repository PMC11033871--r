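Package: pacsmd
Title: Parallel Cascade Selection Molecular Dynamics with Markov State
    Model Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Enhanced conformational sampling by parallel cascade
    selection molecular dynamics (PaCS-MD): cycles of short parallel
    dynamics runs, feature-based ranking of the generated snapshots, and
    reseeding of the best candidates with Maxwell-Boltzmann velocity
    reinitialization.  Includes a built-in Langevin toy-dynamics backend
    with analytic test systems so that every stage runs at desk scale,
    post-processing utilities (representative pathway extraction,
    trajectory refitting, center-of-mass trajectories, feature
    extraction), and Markov state model analysis up to volume-corrected
    standard binding free energies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    igraph,
    stats,
    grDevices,
    utils,
    graphics
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
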