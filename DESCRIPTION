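Package: allerscreen
Title: Protein Allergenicity Screening from Sequence and Surface Epitopes
Version: 0.1.0
Authors@R:
    person("allerscreen", "developers", email = "allerscreen@example.org",
           role = c("aut", "cre"))
Description: Tiered assessment of the allergenic potential of query proteins
    against a reference set of known allergens. Implements an
    entropy-filtered triple-hexamer match rule, a Gluten-like Q-repeat
    compositional fingerprint score, the classical FAO/WHO 35%-identity over
    80-residue linear window rule, and a conformational-epitope stage that
    compares query and allergen over 12 Angstrom surface patches of reference
    3D structures. Includes reference-database management (merge,
    deduplication, greedy identity clustering), a minimal PDB reader with
    Shrake-Rupley style solvent-accessible surface detection, internal
    Needleman-Wunsch/Smith-Waterman alignment with Karlin-Altschul
    significance estimates, a batch workflow with CSV reporting, and fully
    deterministic synthetic-fixture generators so the whole pipeline is
    testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
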