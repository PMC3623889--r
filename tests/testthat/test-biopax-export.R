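translate_fixture_biopax <- function(seed = 1, config = fixture_config(),
                                     level = 3) {
  f <- generate_fixture(seed, config)
  pre <- preprocess_pathway(f$doc, f$store)
  list(f = f, pre = pre,
       x = translate_biopax(pre$doc, f$store, biopax_target(level)))
}

el_kinds <- function(x) vapply(attr(x, "elements"), function(e) e$kind, "")

test_that("entry types map onto the published BioPAX classes", {
  expect_identical(class_for_entry_type("compound", 3), "SmallMolecule")
  expect_identical(class_for_entry_type("enzyme", 3), "Protein")
  expect_identical(class_for_entry_type("gene", 3), "Protein")
  expect_identical(class_for_entry_type("ortholog", 3), "Protein")
  expect_identical(class_for_entry_type("group", 3), "Complex")
  expect_identical(class_for_entry_type("map", 3), "Pathway")
  # level 2 uses lowerCamelCase class names
  expect_identical(class_for_entry_type("compound", 2), "smallMolecule")
  expect_identical(class_for_entry_type("map", 2), "pathway")
  expect_true(is.na(class_for_entry_type("reaction", 3)))
})

test_that("relation subtypes map onto the published vocabulary grid", {
  grid <- list(
    list("activation", 170L, NA_integer_, NA_integer_),
    list("inhibition", 169L, NA_integer_, NA_integer_),
    list("expression", 170L, NA_integer_, 10467L),
    list("repression", 169L, NA_integer_, NA_integer_),
    list("indirect effect", 344L, NA_integer_, NA_integer_),
    list("state change", 168L, NA_integer_, NA_integer_),
    list("binding/association", 177L, 914L, 5488L),
    list("dissociation", 180L, NA_integer_, NA_integer_),
    list("missing interaction", 396L, NA_integer_, NA_integer_),
    list("phosphorylation", 216L, 217L, 16310L),
    list("dephosphorylation", 330L, 203L, 16311L),
    list("glycosylation", 217L, 559L, 70085L),
    list("ubiquitination", 224L, 220L, 16567L),
    list("methylation", 214L, 213L, 32259L))
  for (row in grid) {
    v <- vocabulary_terms(row[[1]])
    expect_identical(v$sbo, row[[2]], info = row[[1]])
    expect_identical(v$mi, row[[3]], info = row[[1]])
    expect_identical(v$go, row[[4]], info = row[[1]])
  }
  expect_error(vocabulary_terms("not-a-subtype"), "vocabulary error")
  # element kinds per level
  expect_identical(vocabulary_terms("expression", 3)$element,
                   "TemplateReaction")
  expect_match(vocabulary_terms("expression", 2)$element, "conversion")
  expect_identical(vocabulary_terms("missing interaction", 2)$element,
                   "physicalInteraction")
})

test_that("small molecules carry formula and weight in dedicated fields", {
  res <- translate_fixture_biopax(1)
  sm_ref <- xml2::xml_find_all(
    res$x, '//*[local-name()="SmallMoleculeReference"]')
  expect_gt(length(sm_ref), 0)
  formulas <- unlist(lapply(sm_ref, function(n) xml2::xml_text(
    xml2::xml_find_all(n, './/*[local-name()="chemicalFormula"]'))))
  expect_gt(length(formulas), 0)
  expect_true(all(grepl("^[A-Za-z0-9()]+$", formulas)))

  # level 2 puts them on the smallMolecule itself
  res2 <- translate_fixture_biopax(1, level = 2)
  sm <- xml2::xml_find_all(res2$x, '//*[local-name()="smallMolecule"]')
  f2 <- unlist(lapply(sm, function(n) xml2::xml_text(
    xml2::xml_find_all(n, './/*[local-name()="CHEMICAL-FORMULA"]'))))
  expect_gt(length(f2), 0)
})

test_that("catalyzed reactions get a Catalysis wiring enzyme to reaction", {
  res <- translate_fixture_biopax(2)
  kinds <- el_kinds(res$x)
  n_modified <- sum(vapply(res$pre$doc$reactions,
                           function(rx) length(rx$modifiers) > 0,
                           logical(1)))
  expect_identical(sum(kinds == "Catalysis"), n_modified)
  expect_identical(sum(kinds == "BiochemicalReaction"),
                   length(res$pre$doc$reactions))
  # every Catalysis/Control has both controller and controlled
  expect_identical(nrow(validate_biopax_structure(res$x)), 0L)

  # an uncatalyzed reaction stays a bare BiochemicalReaction
  st <- resource_store(
    reactions = list("rn:R1" = reaction_record(
      "rn:R1", "cpd:C1 => cpd:C2", FALSE)),
    compounds = list("cpd:C1" = compound_record("cpd:C1", formula = "CH4"),
                     "cpd:C2" = compound_record("cpd:C2", formula = "CH4")))
  doc <- kgml_pathway(
    name = "path:syn9",
    entries = list(kgml_entry(1, "cpd:C1", "compound"),
                   kgml_entry(2, "cpd:C2", "compound")),
    reactions = list(kgml_reaction(
      "rn:R1", "irreversible",
      substrates = list(kgml_participant(1, "cpd:C1")),
      products = list(kgml_participant(2, "cpd:C2")))))
  x <- translate_biopax(doc, st, biopax_target(3))
  kinds2 <- el_kinds(x)
  expect_identical(sum(kinds2 == "Catalysis"), 0L)
  expect_identical(sum(kinds2 == "BiochemicalReaction"), 1L)
})

test_that("participant stoichiometry is annotated on level 3 and level 2", {
  res <- translate_fixture_biopax(3)
  st_el <- Filter(function(e) e$kind == "Stoichiometry",
                  attr(res$x, "elements"))
  # the generator plants coefficients of 2; they must surface here
  coeffs <- unlist(lapply(st_el, function(e)
    vapply(Filter(function(p) p$name == "stoichiometricCoefficient",
                  e$props), function(p) p$value, "")))
  expect_true("2" %in% coeffs)

  res2 <- translate_fixture_biopax(3, level = 2)
  peps <- Filter(function(e) e$kind == "physicalEntityParticipant",
                 attr(res2$x, "elements"))
  coeffs2 <- unlist(lapply(peps, function(e)
    vapply(Filter(function(p) p$name == "STOICHIOMETRIC-COEFFICIENT",
                  e$props), function(p) p$value, "")))
  expect_true("2" %in% coeffs2)
})

test_that("expression becomes TemplateReaction on L3, Conversion+Control on L2", {
  cfg <- clean_fixture_config(relation_subtypes = c("expression",
                                                    "repression"))
  res <- translate_fixture_biopax(4, cfg)
  kinds <- el_kinds(res$x)
  expect_identical(sum(kinds == "TemplateReaction"), 2L)
  expect_identical(sum(kinds == "TemplateReactionRegulation"), 2L)

  res2 <- translate_fixture_biopax(4, cfg, level = 2)
  kinds2 <- el_kinds(res2$x)
  expect_identical(sum(kinds2 == "TemplateReaction"), 0L)
  expect_identical(sum(kinds2 == "conversion"), 2L)
  expect_identical(sum(kinds2 == "control"), 2L)
})

test_that("phosphorylation yields a controlled conversion to a modified state", {
  cfg <- clean_fixture_config(relation_subtypes = "phosphorylation")
  res <- translate_fixture_biopax(5, cfg)
  els <- attr(res$x, "elements")
  kinds <- el_kinds(res$x)
  expect_identical(sum(kinds == "Conversion"), 1L)
  expect_identical(sum(kinds == "Control"), 1L)
  expect_identical(sum(kinds == "ModificationFeature"), 1L)
  expect_identical(sum(kinds == "SequenceModificationVocabulary"), 1L)
  # the modified variant is a synthesized protein with the _p suffix
  expect_true(any(grepl("_p$", names(els)[kinds == "Protein"])))
  # vocabulary carries SBO 216, MI 217 and GO 16310 xrefs
  iv <- els[[grep("^iv_", names(els))[1]]]
  xref_ids <- vapply(Filter(function(p) p$name == "xref", iv$props),
                     function(p) p$value, "")
  targets <- unlist(lapply(els[xref_ids], function(e)
    vapply(Filter(function(p) p$name == "id", e$props),
           function(p) p$value, "")))
  expect_true("SBO:0000216" %in% targets)
  expect_true("MI:0217" %in% targets)
  expect_true("GO:0016310" %in% targets)
})

test_that("binding to a group makes a ComplexAssembly, else a Conversion", {
  # relation target is a plain gene -> generic Conversion
  cfg <- clean_fixture_config(relation_subtypes = "binding/association")
  res <- translate_fixture_biopax(6, cfg)
  expect_identical(sum(el_kinds(res$x) == "ComplexAssembly"), 0L)
  expect_identical(sum(el_kinds(res$x) == "Conversion"), 1L)

  # hand-built relation targeting a group entry -> ComplexAssembly
  f <- generate_fixture(6, cfg)
  gid <- f$manifest$groups[1]
  doc <- f$doc
  doc$relations <- list(kgml_relation(
    doc$relations[[1]]$entry1, gid, "PPrel",
    list(list(name = "binding/association", value = "---"))))
  x <- translate_biopax(preprocess_pathway(doc, f$store)$doc, f$store,
                        biopax_target(3))
  expect_identical(sum(el_kinds(x) == "ComplexAssembly"), 1L)
})

test_that("missing interaction pools both entities; reaction-entry targets wire to interactions", {
  cfg <- clean_fixture_config(relation_subtypes = "missing interaction")
  res <- translate_fixture_biopax(7, cfg)
  kinds <- el_kinds(res$x)
  expect_identical(sum(kinds == "MolecularInteraction"), 1L)
  mi <- attr(res$x, "elements")[[names(kinds)[kinds ==
                                                "MolecularInteraction"]]]
  parts <- Filter(function(p) p$name == "participant", mi$props)
  expect_length(parts, 2)

  # a relation pointing at a reaction-type entry controls that reaction
  res2 <- translate_fixture_biopax(8,
                                   fixture_config(reaction_entries = 1))
  els <- attr(res2$x, "elements")
  ctrl <- Filter(function(e) e$kind == "Control", els)
  controlled <- unlist(lapply(ctrl, function(e)
    vapply(Filter(function(p) p$name == "controlled", e$props),
           function(p) p$value, "")))
  expect_true(any(grepl("^rxn_", controlled)))
})

test_that("complexes attach their components and dangling components fail", {
  res <- translate_fixture_biopax(9, fixture_config(groups = 1))
  els <- attr(res$x, "elements")
  cx <- Filter(function(e) e$kind == "Complex", els)
  expect_length(cx, 1)
  comps <- Filter(function(p) p$name == "component", cx[[1]]$props)
  expect_length(comps, 2)
})

test_that("L2 and L3 translations agree on physical entity counts", {
  for (seed in c(1, 4)) {
    f <- generate_fixture(seed)
    pre <- preprocess_pathway(f$doc, f$store)
    is_entity <- function(k) k %in% c("SmallMolecule", "Protein", "Complex",
                                      "PhysicalEntity", "smallMolecule",
                                      "protein", "complex", "physicalEntity")
    k3 <- el_kinds(translate_biopax(pre$doc, f$store, biopax_target(3)))
    k2 <- el_kinds(translate_biopax(pre$doc, f$store, biopax_target(2)))
    expect_identical(sum(is_entity(k3)), sum(is_entity(k2)))
  }
})

test_that("BioPAX serialization is byte-deterministic and self-validates", {
  mk <- function(level) {
    f <- generate_fixture(11)
    pre <- preprocess_pathway(f$doc, f$store)
    as.character(translate_biopax(pre$doc, f$store, biopax_target(level)))
  }
  expect_identical(mk(3), mk(3))
  expect_identical(mk(2), mk(2))
})

test_that("an empty pathway yields a lone pathway object", {
  doc <- kgml_pathway(name = "path:syn00003", org = "syn", number = "3",
                      title = "empty")
  x <- translate_biopax(doc, resource_store(), biopax_target(3))
  kinds <- el_kinds(x)
  expect_identical(sum(kinds == "Pathway"), 1L)
  expect_error(biopax_target(4), "2 or 3")
})
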