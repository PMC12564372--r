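Package: il18design
Title: Interface-Energetics Driven Design and Trajectory Analysis of IL-18 Variants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for structure-guided design of interleukin-18 (IL-18) variants
    from per-residue interface binding-energy decompositions. Classifies interface
    residues as key, favorable or unfavorable; calibrates an activity-weighted
    mutation score from a mutant validation panel by regressing relative
    free-energy changes on log in-vitro activity; enumerates and ranks single and
    combinatorial amino-acid substitutions; and computes standard molecular
    dynamics trajectory statistics (Kabsch superposition, RMSD, per-residue RMSD,
    RMSF, backbone distance patterns, geometric hydrogen-bond detection and
    charged-group/aromatic contact classification) on multi-model PDB
    trajectories. Seeded synthetic-data generators stand in for the external
    force-field and simulation engines so every stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
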