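Package: qcpost
Title: Post-Processing of Quantum-Chemistry Summaries for Functionalized Polysaccharides
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for the analysis stage that follows an electronic-structure
    calculation: global reactivity descriptors from frontier-orbital energies
    (ionization potential, electron affinity, electronegativity, chemical
    potential, hardness, softness, electrophilicity index, fraction of
    transferred electrons), fragment binding energies with hartree/eV
    conversion and site ranking, Gaussian-broadened density-of-states and
    group-projected DOS curves, and vibrational-band utilities (harmonic
    frequency scaling, monotone band assignment against experimental FTIR
    tables, method/basis-set ranking by band error, differential band
    detection between spectra). Includes a seeded synthetic generator of
    structure-summary records so every stage is testable without an
    electronic-structure run, and bundled reference tables for cellulose
    functionalized with OH, NH2, COOH, CH3, CHO, CN, SH and graphene oxide.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
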