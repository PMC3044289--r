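Package: pharmint
Title: Pharmacological Interaction Mining and Post-Screening Analysis for
    Structure-Based Virtual Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-processing toolkit for structure-based virtual screening.
    Decomposes docked protein-ligand poses into per-residue-group interaction
    energies (electrostatic, hydrogen-bonding, van der Waals), builds binary
    compound-by-residue-group interaction profiles, mines pharmacologically
    conserved interactions against a shuffle null model, re-scores and
    re-ranks screening compounds with a pharmacophore-aware scoring function,
    compares mined interactions with consensus hot spots from active
    compounds, and clusters compounds by interaction profile and atomic
    composition.  Includes a synthetic-pocket and planted-profile generator
    so every stage can be exercised without external structure libraries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    rlang,
    ggplot2,
    generics,
    withr,
    yaml,
    bio3d,
    ChemmineR,
    ape,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
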