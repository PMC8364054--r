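Package: aevbind
Title: Protein-Ligand Binding Affinity Prediction with Atomic Environment Vectors
Version: 0.1.0
Authors@R:
    person("aevbind", "developers", email = "aevbind@example.org", role = c("aut", "cre"))
Description: Structure-based prediction of protein-ligand binding affinity (pK)
    from elements and Cartesian coordinates alone. Binding sites are encoded
    with translation-, rotation- and permutation-invariant atom-centred
    symmetry functions (Behler-Parrinello atomic environment vectors);
    per-element feed-forward neural networks map each atom's environment
    vector to an atomic free-energy contribution, and contributions are summed
    into the pK prediction. Includes a delta-learning mode that corrects
    docking scores converted to the pK scale, consensus ensembles with
    per-prediction uncertainty, CASF-style scoring/ranking/docking/screening
    power metrics with bootstrap confidence intervals, gradient-based
    interpretability, a synthetic-complex generator with known ground truth,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
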