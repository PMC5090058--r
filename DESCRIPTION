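Package: tomodock
Title: Tomographic Docking Scans of Deep Binding Pockets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for tomographic docking: sliding a cubic docking search
    space in fixed increments along the depth axis of a deep binding pocket,
    docking a ligand independently at each step, and analysing the resulting
    pose series. Includes PDB/PDBQT structure handling, principal-axis pocket
    geometry, scan-box planning with per-step atom inclusion tables, a
    deterministic built-in rigid-body docking engine for desk-scale work, an
    AutoDock Vina adapter for production runs, trajectory change-point and
    plateau analysis, and identification of selectivity-filter residues that
    distinguish binders from non-binders. Ships a synthetic-fixture generator
    that plants a tubular pocket with a known engagement niche, constriction
    filter and base site, so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    bio3d,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
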