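# xpath helpers that ignore namespace prefixes
xall <- function(x, name) xml2::xml_find_all(
  x, paste0("//*[local-name()=\"", name, "\"]"))

qattr <- function(nodes, name) vapply(nodes, function(n) {
  a <- xml2::xml_attrs(n)
  hit <- names(a)[sub("^.*:", "", names(a)) == name]
  if (length(hit)) a[[hit[1]]] else NA_character_
}, "")

translate_fixture_sbml <- function(seed = 1, config = fixture_config(),
                                   target = sbml_target("L3V1",
                                                        use_qual = TRUE,
                                                        use_groups = FALSE)) {
  f <- generate_fixture(seed, config)
  pre <- preprocess_pathway(f$doc, f$store)
  list(f = f, pre = pre, x = translate_sbml(pre$doc, f$store, target))
}

test_that("identifiers sanitize into the SBML grammar, injectively", {
  expect_identical(sanitize_sid("hsa:5594"), "hsa_5594")
  expect_identical(sanitize_sid("3dmet"), "_3dmet")
  expect_identical(sanitize_sid("a b.c-d"), "a_b_c_d")
  expect_error(sanitize_sid(""), "empty")
  pool <- kgmlconv:::new_sid_pool()
  expect_identical(pool("a:b"), "a_b")
  expect_identical(pool("a.b"), "a_b_2")   # collision gets a suffix
  expect_identical(pool("a-b"), "a_b_3")
})

test_that("entry types map onto the published SBO accessions", {
  expect_identical(sbo_for_entry_type("compound"), 247L)
  expect_identical(sbo_for_entry_type("enzyme"), 252L)
  expect_identical(sbo_for_entry_type("gene"), 252L)
  expect_identical(sbo_for_entry_type("ortholog"), 252L)
  expect_identical(sbo_for_entry_type("group"), 253L)
  expect_identical(sbo_for_entry_type("map"), 552L)
  expect_true(is.na(sbo_for_entry_type("reaction")))
})

test_that("participant SBO terms follow the reversibility dichotomy", {
  res <- translate_fixture_sbml(1)
  for (rn in xall(res$x, "reaction")) {
    rev <- xml2::xml_attr(rn, "reversible") == "true"
    subs <- xml2::xml_attr(
      xml2::xml_find_all(rn, './/*[local-name()="listOfReactants"]/*'),
      "sboTerm")
    prods <- xml2::xml_attr(
      xml2::xml_find_all(rn, './/*[local-name()="listOfProducts"]/*'),
      "sboTerm")
    if (rev) {
      expect_true(all(c(subs, prods) == "SBO:0000010"))
    } else {
      expect_true(all(subs == "SBO:0000015"))
      expect_true(all(prods == "SBO:0000011"))
    }
    # never a mix of generic and substrate/product terms inside one reaction
    expect_false(any(c(subs, prods) == "SBO:0000010") &&
                   any(c(subs, prods) %in% c("SBO:0000015", "SBO:0000011")))
  }
})

test_that("stoichiometry is copied onto every species reference", {
  res <- translate_fixture_sbml(2)
  refs <- xall(res$x, "speciesReference")
  expect_true(all(!is.na(xml2::xml_attr(refs, "stoichiometry"))))
  # at least one coefficient > 1 flows through from the store equations
  expect_true(any(as.numeric(xml2::xml_attr(refs, "stoichiometry")) > 1))
})

test_that("no species is created for reaction-type entries in core", {
  res <- translate_fixture_sbml(3, fixture_config(reaction_entries = 1))
  rx_entry <- Filter(function(e) e$etype == "reaction", res$pre$doc$entries)
  expect_length(rx_entry, 1)
  sids <- xml2::xml_attr(xall(res$x, "species"), "id")
  expect_false(any(grepl("^rn_RT0001_q$", sids)))
  n_species_entries <- sum(vapply(res$pre$doc$entries, function(e)
    !e$etype %in% c("reaction", "other"), logical(1)))
  expect_length(xall(res$x, "species"), n_species_entries)
  # but it does get a qualitative species, targeted by a transition
  qs <- xall(res$x, "qualitativeSpecies")
  expect_true(any(grepl("^rn_RT0001", qattr(qs, "id"))))
})

test_that("phosphorylation relations become SBO 216 transitions with GO 16310", {
  res <- translate_fixture_sbml(4)
  trs <- xall(res$x, "transition")
  sbo <- xml2::xml_attr(trs, "sboTerm")
  expect_true("SBO:0000216" %in% sbo)
  ph <- trs[[which(sbo == "SBO:0000216")[1]]]
  urns <- xml2::xml_attr(
    xml2::xml_find_all(ph, './/*[local-name()="li"]'), "resource")
  expect_true(any(grepl("GO%3A0016310", urns)))
  # activation: SBO 170 and no GO term
  act <- trs[[which(sbo == "SBO:0000170")[1]]]
  act_urns <- xml2::xml_attr(
    xml2::xml_find_all(act, './/*[local-name()="li"]'), "resource")
  expect_false(any(grepl("urn:miriam:go", act_urns)))
})

test_that("every relation with a mappable subtype yields one transition", {
  res <- translate_fixture_sbml(6, clean_fixture_config())
  expect_length(xall(res$x, "transition"), length(res$pre$doc$relations))
  # inputs and outputs reference the endpoints' qualitative species
  for (tr in xall(res$x, "transition")) {
    ins <- xml2::xml_find_all(tr, './/*[local-name()="input"]')
    outs <- xml2::xml_find_all(tr, './/*[local-name()="output"]')
    expect_length(ins, 1)
    expect_length(outs, 1)
  }
})

test_that("groups become group objects on L3 and HAS_PART species otherwise", {
  cfg <- fixture_config(groups = 1)
  res <- translate_fixture_sbml(7, cfg,
                                sbml_target("L3V1", use_qual = FALSE,
                                            use_groups = TRUE))
  grp <- xall(res$x, "group")
  expect_length(grp, 1)
  expect_length(xml2::xml_find_all(grp[[1]],
                                   './/*[local-name()="member"]'), 2)

  res2 <- suppressWarnings(translate_fixture_sbml(7, cfg,
                                                  sbml_target("L2V4")))
  sp <- xall(res2$x, "species")
  sbo <- xml2::xml_attr(sp, "sboTerm")
  gsp <- sp[[which(sbo == "SBO:0000253")[1]]]
  expect_length(xml2::xml_find_all(
    gsp, './/*[local-name()="hasPart"]//*[local-name()="li"]'), 2)
})

test_that("every species carries an SBO term and a KEGG-derived CV term", {
  res <- translate_fixture_sbml(9)
  for (sp in xall(res$x, "species")) {
    expect_false(is.na(xml2::xml_attr(sp, "sboTerm")))
    urns <- xml2::xml_attr(
      xml2::xml_find_all(sp, './/*[local-name()="li"]'), "resource")
    expect_true(any(grepl("urn:miriam:kegg\\.|urn:miriam:ec-code", urns)))
  }
})

test_that("target constraints are enforced", {
  expect_error(sbml_target("L2V4", use_qual = TRUE), "Level 3")
  expect_error(sbml_target("L2V4", use_groups = TRUE), "Level 3")
  f <- generate_fixture(1)
  pre <- preprocess_pathway(f$doc, f$store)
  expect_warning(translate_sbml(pre$doc, f$store, sbml_target("L2V4")),
                 "cannot be encoded")
})

test_that("SBML serialization is byte-deterministic", {
  mk <- function() {
    f <- generate_fixture(10)
    pre <- preprocess_pathway(f$doc, f$store)
    as.character(translate_sbml(pre$doc, f$store,
                                sbml_target("L3V1", use_qual = TRUE,
                                            use_groups = TRUE)))
  }
  expect_identical(mk(), mk())
})

test_that("an empty pathway still yields a valid document", {
  doc <- kgml_pathway(name = "path:syn00002", org = "syn", number = "2",
                      title = "empty")
  x <- translate_sbml(doc, resource_store(),
                      sbml_target("L3V1", use_qual = TRUE))
  expect_length(xall(x, "species"), 0)
  expect_identical(nrow(validate_sbml_structure(x)), 0L)
})
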