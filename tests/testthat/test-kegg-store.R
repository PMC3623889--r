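test_that("equation grammar handles coefficients, connectors and symbols", {
  eq <- parse_equation("2 cpd:C00001 + cpd:C00002 => cpd:C00003")
  expect_false(eq$reversible)
  expect_identical(eq$substrates[[1]]$coeff, 2)
  expect_identical(eq$substrates[[2]]$coeff, 1)
  expect_identical(eq$products[[1]]$id, "cpd:C00003")

  eq2 <- parse_equation("(n+1) cpd:C00001 <=> (n) cpd:C00002 + cpd:C00009")
  expect_true(eq2$reversible)
  expect_identical(eq2$substrates[[1]]$symbolic, "n+1")
  expect_identical(eq2$substrates[[1]]$coeff, 2)  # value at n = 1
  expect_identical(eq2$products[[1]]$coeff, 1)

  expect_error(parse_equation("cpd:C00001 cpd:C00002"), "two sides")
  expect_error(parse_equation("x cpd:C1 => cpd:C2"), "coefficient")
})

test_that("store directory round-trips and checks referential integrity", {
  f <- generate_fixture(11)
  dir <- withr::local_tempdir()
  write_store(f$store, dir)
  s2 <- load_store(dir)
  expect_equal(s2, f$store)

  # equation citing an unknown compound fails integrity
  bad <- f$store
  bad$reactions[["rn:RTBAD"]] <- list(
    id = "rn:RTBAD", equation = "cpd:NOPE => cpd:CT0001",
    reversible = FALSE, ec_numbers = character(), definition = "")
  dir2 <- withr::local_tempdir()
  write_store(bad, dir2)
  expect_error(load_store(dir2), "unknown compound")

  # empty directory fails with the missing file named
  expect_error(load_store(withr::local_tempdir()), "reactions.txt")
})

test_that("compound lookups follow aliases to the canonical record", {
  st <- resource_store(
    compounds = list("cpd:C00031" = compound_record("cpd:C00031",
                                                    names = "D-Glucose",
                                                    formula = "C6H12O6")),
    aliases = c("gl:G10481" = "cpd:C00031"))
  rec <- store_lookup(st, "compound", "gl:G10481")
  expect_identical(rec$id, "cpd:C00031")
  expect_null(store_lookup(st, "reaction", "rn:R99999"))
  expect_identical(canonical_compound_id(st, "gl:G10481"), "cpd:C00031")
  # identity and idempotence
  expect_identical(canonical_compound_id(st, "cpd:C00031"), "cpd:C00031")
  expect_identical(
    canonical_compound_id(st, canonical_compound_id(st, "gl:G10481")),
    canonical_compound_id(st, "gl:G10481"))
})

test_that("gene lookups return the stored record", {
  f <- generate_fixture(2)
  gid <- names(f$store$genes)[1]
  expect_identical(store_lookup(f$store, "gene", gid)$id, gid)
})

test_that("alias closure: lookup agrees before and after canonicalization", {
  f <- generate_fixture(4)
  for (id in c(names(f$store$aliases), names(f$store$compounds))) {
    a <- store_lookup(f$store, "compound", id)
    b <- store_lookup(f$store, "compound", canonical_compound_id(f$store, id))
    expect_identical(a, b)
  }
})

test_that("fixture generation is deterministic and honors its config", {
  f1 <- generate_fixture(1)
  f2 <- generate_fixture(1)
  expect_identical(f1, f2)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_fixture(f1, d1); write_fixture(f2, d2)
  for (rel in c("pathway.xml", "store/reactions.txt", "store/compounds.txt",
                "store/genes.txt", "store/aliases.tsv", "manifest.yaml"))
    expect_identical(readLines(file.path(d1, rel)),
                     readLines(file.path(d2, rel)))

  cfg <- fixture_config(n_reactions = 6, bundled = 2)
  fb <- generate_fixture(3, cfg)
  n_bundled <- sum(vapply(fb$doc$reactions,
                          function(rx) length(rx$ids) >= 2, logical(1)))
  expect_identical(n_bundled, 2L)
  expect_length(fb$manifest$bundled, 2L)
})

test_that("contradictory fixture configurations are refused", {
  expect_error(fixture_config(n_reactions = 2, bundled = 2,
                              missing_participants = 2),
               "exceed n_reactions")
  expect_error(fixture_config(n_reactions = 1, bundled = 0,
                              missing_participants = 0, glycan_aliases = 0,
                              duplicates = 0, missing_enzyme_links = 0),
               "at least 2 genes")
  expect_error(fixture_config(n_reactions = -1), "non-negative")
})

test_that("planted imbalance yields exactly the manifest's per-element diff", {
  cfg <- fixture_config(planted_imbalance = 1, missing_participants = 0,
                        bundled = 1, glycan_aliases = 1)
  f <- generate_fixture(9, cfg)
  expect_length(f$manifest$imbalanced, 1L)
  planted <- f$manifest$imbalanced[[1]]
  # independent check: recount elements of each equation side from the
  # stored formulas, for every reaction
  n_bad <- 0L
  for (rec in f$store$reactions) {
    eq <- parse_equation(rec$equation)
    count_side <- function(side) {
      tot <- numeric()
      for (p in side) {
        cid <- canonical_compound_id(f$store, p$id)
        cc <- parse_formula(f$store$compounds[[cid]]$formula)$counts
        for (el in names(cc))
          tot[el] <- (if (el %in% names(tot)) tot[[el]] else 0) +
            cc[[el]] * p$coeff
      }
      tot
    }
    s <- count_side(eq$substrates); p <- count_side(eq$products)
    els <- union(names(s), names(p))
    diff <- vapply(els, function(el)
      (if (el %in% names(s)) s[[el]] else 0) -
      (if (el %in% names(p)) p[[el]] else 0), numeric(1))
    if (any(diff != 0)) {
      n_bad <- n_bad + 1L
      expect_identical(rec$id, planted$reaction)
      expect_equal(as.list(diff[diff != 0]), planted$expected_diff)
    }
  }
  expect_identical(n_bad, 1L)
})
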