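Package: thermotax
Title: Mechanistic Modeling and Behavioral Analysis of Bacterial Thermotaxis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Models bidirectional thermotaxis of Escherichia coli with mixed
    Tar/Tsr chemoreceptor teams. Implements a two-state (MWC-type) free-energy
    model of receptor-team activity with temperature- and methylation-dependent
    free energies, methylation adaptation kinetics that saturate as methylation
    sites fill, steady-state adaptation solvers, trimer-ensemble averaging and
    normalized thermal-response curves with inversion-temperature detection.
    Also provides the accompanying behavioral and growth analyses: particle
    filtering and nearest-neighbour track linking for microfluidic assays,
    motility and path-length filters, cross-channel position histograms, the
    thermal migration coefficient, linear temperature-gradient mapping, and
    growth-curve metrics (maximal specific growth rate, growth delay). A
    seeded synthetic-data module generates trajectories, spurious detections,
    temperature gradients and logistic growth curves with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
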