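Package: ScaffoldScreen
Title: Scaffold-Based Virtual Screening and Docking Post-Processing for
    Drug Repurposing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A hit-to-lead pipeline for scaffold-based repurposing screens
    of approved-drug libraries. Filters a SMILES/SDF/CSV compound library
    for a substructure query (by default the propane-1-sulfonic acid core
    of tramiprosate), computes molecular descriptors, electrotopological
    state (E-state) fingerprints, Tanimoto similarity matrices and
    hierarchical cluster trees, converts docking binding energies into
    inhibition constants and ligand efficiencies, scores blood-brain
    barrier partitioning (logBB) with the Clark and Rishton linear models,
    post-processes MM-PBSA/GBSA output tables (entropy-enthalpy
    compensation audits, per-residue and pairwise hot-residue calls,
    buried surface area), and provides the correlation/regression analysis
    and synthetic-data generators needed to test every stage without
    external docking or molecular-dynamics software.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    ChemmineR,
    ChemmineOB,
    ape,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
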