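Package: kgmlconv
Title: Compile KEGG KGML Pathways into Annotated SBML and BioPAX Models
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Parses KGML-formatted KEGG pathway documents, corrects the
    structural shortcuts KEGG takes for visualization (bundled reactions,
    missing reaction participants, duplicated graphical entries, white
    organism-unspecific nodes, pathway-reference entries, compound-relations
    shadowing reactions, glycan identifiers standing in for compounds),
    completes reaction stoichiometry from an offline resource store of
    reaction equations, compound formulas and gene records, checks the
    per-element atom balance of every completed reaction, and serializes the
    result as richly annotated SBML (Level 2 Version 4 core, or Level 3
    Version 1 with the qualitative-models and groups packages) or BioPAX
    (Levels 2 and 3) with SBO/GO/MI vocabulary terms and MIRIAM identifiers.
    Includes a deterministic synthetic-fixture generator producing matched
    pathway/store pairs with planted defects for converter validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    xml2,
    jsonlite,
    yaml,
    tibble,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
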