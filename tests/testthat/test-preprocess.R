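test_that("pruning removes map links, white nodes, then orphans", {
  cfg <- fixture_config(maplinks = 2, white_nodes = 1, orphans = 2)
  f <- generate_fixture(21, cfg)
  n0 <- length(f$doc$entries)
  n_maplink_rel <- sum(vapply(f$doc$relations,
                              function(r) r$rtype == "maplink", logical(1)))
  expect_identical(n_maplink_rel, 2L)

  doc <- prune_entries(f$doc, preprocess_options(remove_orphans = FALSE))
  expect_identical(length(doc$entries), n0 - 2L - 1L)
  expect_false(any(vapply(doc$relations, function(r) r$rtype == "maplink",
                          logical(1))))
  # white compound entries are untouched (whiteness applies to gene products)
  expect_true(any(vapply(doc$entries, function(e)
    e$etype == "compound" && !is.null(e$graphics) &&
      toupper(e$graphics$bgcolor) == "#FFFFFF", logical(1))))

  doc2 <- prune_entries(f$doc, preprocess_options(remove_orphans = TRUE))
  expect_identical(length(doc2$entries), n0 - 2L - 1L - 2L)
  remaining <- vapply(doc2$entries, function(e) e$id, integer(1))
  expect_false(any(f$manifest$orphans %in% remaining))

  # all flags off is the identity
  off <- preprocess_options(remove_pathway_refs = FALSE,
                            remove_white_nodes = FALSE,
                            remove_orphans = FALSE)
  expect_equal(prune_entries(f$doc, off), f$doc, ignore_attr = TRUE)
})

test_that("unbundling conserves the reaction-id multiset", {
  f <- generate_fixture(8, fixture_config(n_reactions = 6, bundled = 2))
  before <- reaction_id_multiset(f$doc)
  k <- vapply(f$doc$reactions, function(rx) length(rx$ids), integer(1))
  doc <- unbundle_reactions(f$doc)
  expect_true(all(vapply(doc$reactions, function(rx) length(rx$ids) == 1L,
                         logical(1))))
  expect_identical(length(doc$reactions),
                   length(f$doc$reactions) + sum(k - 1L))
  expect_identical(reaction_id_multiset(doc), before)
  # already-unbundled documents are unchanged
  expect_equal(unbundle_reactions(doc), doc, ignore_attr = TRUE)
})

test_that("completion restores missing participants with equation stoichiometry", {
  f <- generate_fixture(13, fixture_config(missing_participants = 1))
  doc <- unbundle_reactions(f$doc)
  planted <- f$manifest$missing[[1]]
  rx <- find_reaction(doc, planted$reaction)
  expect_false(planted$kegg_id %in%
                 vapply(rx$products, function(p) p$kegg_id, ""))
  res <- complete_reaction(doc, rx, f$store)
  got <- Filter(function(p) p$kegg_id == planted$kegg_id,
                res$reaction$products)
  expect_length(got, 1)
  expect_identical(got[[1]]$stoichiometry, as.numeric(planted$stoichiometry))
  expect_true(any(res$log$action == "add-participant"))
  # the species had no entry: one was created
  expect_true(any(res$log$action == "add-entry"))
  added_id <- got[[1]]$entry_id
  expect_identical(kgmlconv:::get_entry(res$doc, added_id)$names,
                   planted$kegg_id)
})

test_that("completion copies coefficients and is the identity when complete", {
  st <- resource_store(
    reactions = list("rn:R1" = reaction_record(
      "rn:R1", "2 cpd:C1 + cpd:C2 => cpd:C3", FALSE)),
    compounds = list("cpd:C1" = compound_record("cpd:C1", formula = "CH4"),
                     "cpd:C2" = compound_record("cpd:C2", formula = "O2"),
                     "cpd:C3" = compound_record("cpd:C3", formula = "C2H8O2")))
  doc <- kgml_pathway(
    name = "path:syn9",
    entries = list(kgml_entry(1, "cpd:C1", "compound"),
                   kgml_entry(2, "cpd:C2", "compound"),
                   kgml_entry(3, "cpd:C3", "compound")),
    reactions = list(kgml_reaction(
      "rn:R1", "irreversible",
      substrates = list(kgml_participant(1, "cpd:C1"),
                        kgml_participant(2, "cpd:C2")),
      products = list(kgml_participant(3, "cpd:C3")))))
  res <- complete_reaction(doc, doc$reactions[[1]], st)
  expect_identical(res$reaction$substrates[[1]]$stoichiometry, 2)
  # a second pass changes nothing and logs nothing
  doc2 <- res$doc; doc2$reactions[[1]] <- res$reaction
  res2 <- complete_reaction(doc2, doc2$reactions[[1]], st)
  expect_equal(res2$reaction, res$reaction, ignore_attr = TRUE)
  expect_identical(nrow(res2$log), 0L)
})

test_that("completion on a store-absent reaction leaves it untouched", {
  f <- generate_fixture(3)
  doc <- unbundle_reactions(f$doc)
  rx <- doc$reactions[[1]]
  rx$ids <- "rn:RMISSING"
  res <- complete_reaction(doc, rx, f$store)
  expect_equal(res$reaction, rx, ignore_attr = TRUE)
  expect_identical(res$log$action, "error")
})

test_that("completion wires unlinked enzymes back through their EC number", {
  f <- generate_fixture(17, fixture_config(missing_enzyme_links = 1))
  planted <- f$manifest$unwired_enzymes[[1]]
  doc <- unbundle_reactions(f$doc)
  rx <- find_reaction(doc, planted$reaction)
  expect_false(planted$entry %in% rx$modifiers)
  res <- complete_reaction(doc, rx, f$store)
  expect_true(planted$entry %in% res$reaction$modifiers)
  expect_true(any(res$log$action == "add-modifier"))
})

test_that("glycan canonicalization rewrites identifiers everywhere", {
  st <- resource_store(
    compounds = list("cpd:C1" = compound_record("cpd:C1", formula = "CH4")),
    aliases = c("gl:G1" = "cpd:C1"))
  doc <- kgml_pathway(
    name = "path:syn9",
    entries = list(kgml_entry(1, "gl:G1", "compound"),
                   kgml_entry(2, "cpd:C1", "compound")),
    reactions = list(kgml_reaction(
      "rn:R1", "irreversible",
      substrates = list(kgml_participant(1, "gl:G1")),
      products = list(kgml_participant(2, "cpd:C1")))))
  out <- canonicalize_glycans(doc, st)
  expect_identical(out$entries[[1]]$names, "cpd:C1")
  expect_identical(out$entries[[2]]$names, "cpd:C1")
  expect_identical(out$reactions[[1]]$substrates[[1]]$kegg_id, "cpd:C1")
  # alias-free documents are unchanged
  st0 <- resource_store()
  expect_equal(canonicalize_glycans(doc, st0), doc, ignore_attr = TRUE)
})

test_that("duplicate entries merge into one representative catalyzing both", {
  doc <- kgml_pathway(
    name = "path:syn9",
    entries = list(
      kgml_entry(1, "hsa:5594", "gene", reaction_attr = "rn:R1",
                 graphics = kgml_graphics(label = "MAPK1")),
      kgml_entry(2, "hsa:5594", "gene", reaction_attr = "rn:R2",
                 graphics = kgml_graphics(label = "MAPK1")),
      kgml_entry(3, "cpd:C1", "compound"),
      kgml_entry(4, "cpd:C2", "compound")),
    relations = list(
      kgml_relation(1, 3, "PPrel", list(list(name = "activation",
                                             value = "-->"))),
      kgml_relation(2, 3, "PPrel", list(list(name = "activation",
                                             value = "-->")))),
    reactions = list(
      kgml_reaction("rn:R1", "irreversible",
                    substrates = list(kgml_participant(3, "cpd:C1")),
                    products = list(kgml_participant(4, "cpd:C2")),
                    modifiers = 1L),
      kgml_reaction("rn:R2", "irreversible",
                    substrates = list(kgml_participant(4, "cpd:C2")),
                    products = list(kgml_participant(3, "cpd:C1")),
                    modifiers = 2L)))
  res <- merge_duplicate_entries(doc)
  expect_length(res$doc$entries, 3)
  expect_identical(res$doc$reactions[[1]]$modifiers, 1L)
  expect_identical(res$doc$reactions[[2]]$modifiers, 1L)
  # the representative unions the copies' reaction attributes
  expect_setequal(res$doc$entries[[1]]$reaction_attr, c("rn:R1", "rn:R2"))
  # duplicated relations collapse
  expect_length(res$doc$relations, 1)
  expect_identical(res$merge_map$groups, list(c(1L, 2L)))
  expect_identical(unname(res$merge_map$representative[["2"]]), 1L)

  # all-distinct documents keep an identity merge map
  f <- generate_fixture(6, clean_fixture_config())
  res2 <- merge_duplicate_entries(f$doc)
  expect_length(res2$merge_map$groups, 0)
  expect_equal(res2$doc, f$doc, ignore_attr = TRUE)
})

test_that("planted duplicate pairs reduce the entry count by their number", {
  for (seed in c(2, 9)) {
    f <- generate_fixture(seed, fixture_config(duplicates = 1))
    res <- merge_duplicate_entries(f$doc)
    expect_identical(length(res$doc$entries),
                     length(f$doc$entries) - length(f$manifest$duplicates))
  }
})

test_that("compound-relations vanish only when reactions are present", {
  f <- generate_fixture(12, fixture_config(compound_relations = 2))
  expect_length(f$manifest$compound_relations, 2)
  out <- dedupe_compound_relations(f$doc)
  expect_identical(length(out$relations), length(f$doc$relations) - 2L)

  no_rx <- f$doc
  no_rx$reactions <- list()
  expect_identical(length(dedupe_compound_relations(no_rx)$relations),
                   length(f$doc$relations))

  # mixed-subtype relations are kept
  doc <- f$doc
  doc$relations <- list(kgml_relation(
    f$doc$relations[[1]]$entry1, f$doc$relations[[1]]$entry2, "PPrel",
    list(list(name = "compound", value = "5"),
         list(name = "activation", value = "-->"))))
  expect_length(dedupe_compound_relations(doc)$relations, 1)
})

test_that("the full pipeline is the identity on defect-free fixtures", {
  for (seed in c(1, 5, 23)) {
    f <- generate_fixture(seed, clean_fixture_config())
    pre <- preprocess_pathway(f$doc, f$store)
    expect_identical(nrow(pre$log), 0L)
    expect_equal(pre$doc, f$doc, ignore_attr = TRUE)
    expect_length(pre$merge_map$groups, 0)
  }
})

test_that("after preprocessing every reaction matches its store equation", {
  for (seed in 1:10) {
    f <- generate_fixture(seed, fixture_config(planted_imbalance = 0))
    pre <- preprocess_pathway(f$doc, f$store)
    for (rx in pre$doc$reactions) {
      expect_length(rx$ids, 1)
      rec <- f$store$reactions[[rx$ids]]
      expect_identical(rx$rtype,
                       if (rec$reversible) "reversible" else "irreversible")
      eq <- parse_equation(rec$equation)
      side <- function(refs) sort(vapply(refs, function(p)
        paste0(canonical_compound_id(f$store, p$kegg_id), ":",
               p$stoichiometry), ""))
      side_eq <- function(ps) sort(vapply(ps, function(p)
        paste0(canonical_compound_id(f$store, p$id), ":", p$coeff), ""))
      expect_identical(side(rx$substrates), side_eq(eq$substrates))
      expect_identical(side(rx$products), side_eq(eq$products))
    }
  }
})

test_that("entry-count bookkeeping is fully accounted by the log", {
  f <- generate_fixture(31)
  pre <- preprocess_pathway(f$doc, f$store,
                            preprocess_options(remove_orphans = TRUE))
  removed <- sum(pre$log$action == "remove-entry")
  added <- sum(pre$log$action == "add-entry")
  merged <- sum(lengths(pre$merge_map$groups) - 1L)
  expect_identical(length(pre$doc$entries),
                   length(f$doc$entries) - removed + added - merged)
})
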