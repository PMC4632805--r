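Package: aoxpep
Title: Antioxidant Peptide Scoring, Reactivity Descriptors and
    Trolox-Equivalent Assay Quantification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for structure-function analysis of antioxidant peptides.
    Implements an empirical integral scoring parameter for ranking peptides by
    predicted antioxidant activity in ORAC (peroxyl radical) and TEAC (ABTS
    cation radical) assays, a conceptual-DFT descriptor calculus
    (electronegativity, hardness, electrophilicity, Koopmans and adiabatic
    ionization potentials, HOMO-LUMO gap, bond dissociation energy, Mulliken
    charge attack-site ranking) over tabulated quantum-chemistry outputs,
    additive/synergic/infra-additive classification of dipeptide antioxidant
    capacity, trolox-equivalent quantification from plate-reader kinetics
    (TEAC absorbance decline, ORAC net area under the curve), a
    descriptor-activity correlation screen with an ionogenic-residue exclusion
    rule, and seeded simulators for every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
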