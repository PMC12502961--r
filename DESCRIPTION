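Package: ringprop
Title: Electronic Property Prediction for Cyclic Molecules with an
    Edge-Aware Graph Attention Network
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for predicting five electronic properties of mono-, bi-
    and tricyclic organic molecules (HOMO-LUMO gap, vertical ionization
    potential, vertical electron affinity, and aqueous oxidation and
    reduction potentials) from 2D molecular graphs. Provides a seeded
    generator of valid cyclic test molecules, a Hueckel molecular-orbital
    label oracle with planted linear redox relations, atom/bond graph
    featurization, a multi-task edge-aware graph attention regressor
    trained by backpropagation, thermodynamic-cycle redox computation from
    Gibbs free energies, evaluation utilities (learning curves,
    ring-stratified metrics, worst-error analysis), circular fingerprints
    with Tanimoto similarity, and PCA-based embedding-space analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineOB,
    graphics,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
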