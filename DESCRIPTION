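Package: dsredox
Title: Oxidation Potentials and Hole Delocalization in Double-Stranded DNA Ensembles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Marcus-theory one-electron oxidation potentials from ensembles of
    vertical ionization and attachment energies, per-nucleobase hole
    distributions and intermolecular delocalization numbers, and
    RMSD-clustering based representative-structure estimation with
    convergence diagnostics, for model double-stranded DNA duplexes.
    Includes a seeded synthetic trajectory generator with closed-form ground
    truth so that every stage of the analysis is testable without molecular
    dynamics or electronic-structure calculations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    bio3d,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
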