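# Deterministic synthetic fixture generator: matched (pathway, store) pairs
# with planted defects of every kind the preprocessing pipeline corrects.
# All identifiers live in a reserved synthetic namespace (cpd:CT####,
# rn:RT####, syn:1####, gl:GT####, ko:KT####, path:syn####) so they can
# never collide with real KEGG identifiers. Store equations are
# atom-balanced by construction (each product's formula is the exact
# stoichiometry-weighted sum of its substrates') unless an imbalance is
# planted, in which case the expected per-element difference is computed
# independently at build time and recorded in the manifest.

RELATION_SUBTYPE_VALUES <- c(
  "activation" = "-->", "inhibition" = "--|", "expression" = "-->",
  "repression" = "--|", "indirect effect" = "..>", "state change" = "...",
  "binding/association" = "---", "dissociation" = "-+-",
  "missing interaction" = "-/-", "phosphorylation" = "+p",
  "dephosphorylation" = "-p", "glycosylation" = "+g",
  "ubiquitination" = "+u", "methylation" = "+m")

#' Fixture generator configuration
#'
#' Counts of planted features. Each defect class is assigned to a distinct
#' reaction so defects never interact; the generator refuses contradictory
#' configurations.
#'
#' @param n_reactions Number of base reactions (one catalyzing gene each).
#' @param bundled Reaction objects carrying two KEGG reaction ids (the
#'   partner reaction shares the base reaction's equation).
#' @param missing_participants Reactions whose KGML omits one product
#'   relative to the store equation.
#' @param duplicates Gene entries duplicated graphically (the copy
#'   catalyzes a different reaction when one exists).
#' @param white_nodes Ortholog entries rendered with white background
#'   (organism-unspecific).
#' @param maplinks Entries of type `map` plus a maplink relation each.
#' @param orphans Compound entries participating in nothing.
#' @param groups Group entries with two gene components.
#' @param reaction_entries Entries of type `reaction` targeted by a
#'   relation.
#' @param relation_subtypes Character vector of relation subtypes to plant,
#'   one relation each (default: the full closed vocabulary).
#' @param compound_relations Pure subtype-`compound` relations shadowing
#'   reactions.
#' @param glycan_aliases Reactions whose product is referenced by a glycan
#'   identifier aliased to the compound identifier in the store.
#' @param missing_enzyme_links Genes whose KGML entry lacks the reaction
#'   attribute; completion must wire them back via their EC number.
#' @param planted_imbalance Reactions whose product formula is perturbed so
#'   the store-side atom balance is nonzero.
#' @return A list of class `fixture_config`.
#' @export
fixture_config <- function(n_reactions = 5, bundled = 1,
                           missing_participants = 1, duplicates = 1,
                           white_nodes = 1, maplinks = 1, orphans = 1,
                           groups = 1, reaction_entries = 1,
                           relation_subtypes = names(RELATION_SUBTYPE_VALUES),
                           compound_relations = 1, glycan_aliases = 1,
                           missing_enzyme_links = 1, planted_imbalance = 0) {
  cfg <- list(n_reactions = n_reactions, bundled = bundled,
              missing_participants = missing_participants,
              duplicates = duplicates, white_nodes = white_nodes,
              maplinks = maplinks, orphans = orphans, groups = groups,
              reaction_entries = reaction_entries,
              relation_subtypes = relation_subtypes,
              compound_relations = compound_relations,
              glycan_aliases = glycan_aliases,
              missing_enzyme_links = missing_enzyme_links,
              planted_imbalance = planted_imbalance)
  if (any(vapply(cfg[names(cfg) != "relation_subtypes"], function(x) x < 0,
                 logical(1))))
    stop("fixture config error: counts must be non-negative", call. = FALSE)
  # defect classes occupy disjoint reactions
  if (missing_participants + bundled + glycan_aliases + planted_imbalance >
      n_reactions)
    stop("fixture config error: defect classes (missing_participants + ",
         "bundled + glycan_aliases + planted_imbalance) exceed n_reactions",
         call. = FALSE)
  if (duplicates + missing_enzyme_links > n_reactions)
    stop("fixture config error: duplicates + missing_enzyme_links exceed ",
         "the number of genes (= n_reactions)", call. = FALSE)
  if ((groups > 0 || length(relation_subtypes) > 0 ||
       compound_relations > 0) && n_reactions < 2)
    stop("fixture config error: groups/relations require at least 2 genes",
         call. = FALSE)
  structure(cfg, class = "fixture_config")
}

counts_to_formula <- function(counts) {
  counts <- counts[counts > 0]
  ord <- c(intersect(c("C", "H"), names(counts)),
           sort(setdiff(names(counts), c("C", "H"))))
  paste(vapply(ord, function(el)
    paste0(el, if (counts[[el]] > 1) format(counts[[el]]) else ""), ""),
    collapse = "")
}

#' Generate a matched synthetic pathway / store fixture
#'
#' Deterministic for a fixed `(seed, config)`: repeated calls produce
#' field-equal documents and byte-equal serializations. The returned
#' manifest records every planted defect with the evidence a test harness
#' needs to verify its detection and repair (omitted participants with
#' their stoichiometry, bundle id sets, duplicate entry id pairs, expected
#' per-element atom differences, alias mappings, unwired enzyme entries).
#'
#' @param seed Integer seed for the generator's private RNG stream.
#' @param config A [fixture_config()].
#' @return A list with `doc` (a [kgml_pathway()]), `store`
#'   (a `resource_store`) and `manifest` (a list).
#' @export
generate_fixture <- function(seed = 1L, config = fixture_config()) {
  stopifnot(inherits(config, "fixture_config"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)

  nR <- config$n_reactions
  manifest <- list(seed = seed, config = unclass(config))

  # --- substrate compound pool -------------------------------------------
  n_pool <- max(4L, nR + 2L)
  compounds <- list()
  for (i in seq_len(n_pool)) {
    counts <- c(C = sample(1:6, 1), H = sample(2:12, 1),
                O = sample(1:6, 1), N = sample(0:3, 1))
    f <- counts_to_formula(counts)
    id <- sprintf("cpd:CT%04d", i)
    compounds[[id]] <- compound_record(
      id = id, names = sprintf("synthetic metabolite %d", i), formula = f,
      mol_weight = round(formula_weight(f), 2),
      xrefs = list("ChEBI" = as.character(90000 + i),
                   "PubChem" = as.character(70000 + i)))
  }
  pool_ids <- names(compounds)

  # --- reactions, products, genes ----------------------------------------
  # disjoint defect slots
  slot <- seq_len(nR)
  miss_rx <- head(slot, config$missing_participants)
  slot <- setdiff(slot, miss_rx)
  bundle_rx <- head(slot, config$bundled)
  slot <- setdiff(slot, bundle_rx)
  glycan_rx <- head(slot, config$glycan_aliases)
  slot <- setdiff(slot, glycan_rx)
  imbalance_rx <- head(slot, config$planted_imbalance)

  reactions <- list()
  genes <- list()
  aliases <- character()
  rx_subs <- list()   # per reaction: list(id, coeff)
  rx_prod <- list()
  manifest$imbalanced <- list()
  manifest$glycan_aliases <- character()

  for (j in seq_len(nR)) {
    sub_ids <- sample(pool_ids, 2)
    coeffs <- sample(1:2, 2, replace = TRUE)
    prod_counts <- sum_counts(lapply(sub_ids, function(id)
      parse_formula(compounds[[id]]$formula)$counts), coeffs)
    prod_id <- sprintf("cpd:CT%04d", n_pool + j)
    prod_formula_counts <- prod_counts
    expected_diff <- NULL
    if (j %in% imbalance_rx) {
      # product formula gains one water's worth of atoms; substrate - product
      # is then {H: -2, O: -1}, computed here by independent element count
      perturbed <- prod_counts
      perturbed["H"] <- (if ("H" %in% names(perturbed)) perturbed[["H"]] else 0) + 2
      perturbed["O"] <- (if ("O" %in% names(perturbed)) perturbed[["O"]] else 0) + 1
      prod_formula_counts <- perturbed
      ed <- numeric()
      for (el in union(names(prod_counts), names(perturbed))) {
        d <- (if (el %in% names(prod_counts)) prod_counts[[el]] else 0) -
          (if (el %in% names(perturbed)) perturbed[[el]] else 0)
        if (d != 0) ed[el] <- d
      }
      expected_diff <- ed[order(names(ed))]
    }
    f <- counts_to_formula(prod_formula_counts)
    compounds[[prod_id]] <- compound_record(
      id = prod_id, names = sprintf("synthetic product %d", j), formula = f,
      mol_weight = round(formula_weight(f), 2),
      xrefs = list("ChEBI" = as.character(90000 + n_pool + j)))
    if (!is.null(expected_diff))
      manifest$imbalanced[[length(manifest$imbalanced) + 1L]] <-
        list(reaction = sprintf("rn:RT%04d", j),
             expected_diff = as.list(expected_diff))

    written_prod_id <- prod_id
    if (j %in% glycan_rx) {
      gl <- sprintf("gl:GT%04d", j)
      aliases[[gl]] <- prod_id
      written_prod_id <- gl
      manifest$glycan_aliases[[gl]] <- prod_id
    }

    rid <- sprintf("rn:RT%04d", j)
    reversible <- stats::runif(1) < 0.5
    eq <- paste0(
      paste(vapply(seq_along(sub_ids), function(k)
        paste0(if (coeffs[k] > 1) paste0(coeffs[k], " "), sub_ids[k]), ""),
        collapse = " + "),
      if (reversible) " <=> " else " => ", prod_id)
    ec <- sprintf("%d.%d.1.%d", sample(1:6, 1), sample(1:9, 1), j)
    reactions[[rid]] <- reaction_record(
      id = rid, equation = eq, reversible = reversible, ec_numbers = ec,
      definition = sprintf("synthetic reaction %d", j))
    rx_subs[[rid]] <- Map(function(id, k) list(id = id, coeff = k),
                          sub_ids, coeffs)
    rx_prod[[rid]] <- list(list(id = written_prod_id, coeff = 1))

    gid <- sprintf("syn:1%04d", j)
    genes[[gid]] <- gene_record(
      id = gid, symbols = sprintf("SYG%d", j),
      description = sprintf("synthetic enzyme %d", j), ec_numbers = ec,
      xrefs = list("NCBI-GeneID" = as.character(500000 + j),
                   "UniProt" = sprintf("P%05d", 10000 + j),
                   "Ensembl" = sprintf("ENSSYG%011d", j)))
  }

  # bundle partners: same equation as the base reaction, own id and EC
  manifest$bundled <- list()
  for (j in bundle_rx) {
    base <- sprintf("rn:RT%04d", j)
    pid <- sprintf("rn:RTB%03d", j)
    br <- reactions[[base]]
    reactions[[pid]] <- reaction_record(
      id = pid, equation = br$equation, reversible = br$reversible,
      ec_numbers = sprintf("9.9.9.%d", j),
      definition = sprintf("synthetic bundled partner of reaction %d", j))
    manifest$bundled[[length(manifest$bundled) + 1L]] <- c(base, pid)
  }

  # orphan compounds exist only in the store + as dangling entries
  orphan_cpds <- character()
  for (k in seq_len(config$orphans)) {
    id <- sprintf("cpd:CTO%03d", k)
    compounds[[id]] <- compound_record(
      id = id, names = sprintf("synthetic orphan metabolite %d", k),
      formula = "C2H6O", mol_weight = round(formula_weight("C2H6O"), 2))
    orphan_cpds <- c(orphan_cpds, id)
  }

  store <- resource_store(reactions = reactions, compounds = compounds,
                          genes = genes, aliases = aliases)

  # --- KGML document ------------------------------------------------------
  next_id <- 0L
  nid <- function() { next_id <<- next_id + 1L; next_id }
  entries <- list()
  add_entry <- function(...) {
    e <- kgml_entry(...)
    entries[[length(entries) + 1L]] <<- e
    e$id
  }

  # compound entries for every species written in a KGML reaction
  written_ids <- unique(unlist(c(
    lapply(rx_subs, function(ps) vapply(ps, function(p) p$id, "")),
    lapply(rx_prod, function(ps) vapply(ps, function(p) p$id, "")))))
  omitted <- character()
  manifest$missing <- list()
  for (j in miss_rx) {
    rid <- sprintf("rn:RT%04d", j)
    om <- rx_prod[[rid]][[1]]
    manifest$missing[[length(manifest$missing) + 1L]] <-
      list(reaction = rid, kegg_id = om$id, side = "product",
           stoichiometry = om$coeff)
    omitted <- c(omitted, om$id)
  }
  # species only ever appearing as an omitted participant get no entry
  present_elsewhere <- unique(unlist(c(
    lapply(rx_subs, function(ps) vapply(ps, function(p) p$id, "")),
    lapply(rx_prod[setdiff(names(rx_prod),
                           vapply(manifest$missing, `[[`, "", "reaction"))],
           function(ps) vapply(ps, function(p) p$id, "")))))
  cpd_entry <- integer()
  for (id in written_ids) {
    if (id %in% omitted && !id %in% present_elsewhere) next
    cpd_entry[[id]] <- add_entry(
      id = nid(), names = id, etype = "compound",
      graphics = kgml_graphics(label = id, bgcolor = "#FFFFFF",
                               fgcolor = "#000000", x = 8 * next_id, y = 40,
                               width = 8, height = 8, shape = "circle"))
  }

  # gene entries (one per reaction); the first `missing_enzyme_links` from
  # the tail are left unwired, duplicates come from the head
  gene_entry <- integer()
  unwired <- tail(seq_len(nR), config$missing_enzyme_links)
  for (j in seq_len(nR)) {
    gid <- sprintf("syn:1%04d", j)
    rid <- sprintf("rn:RT%04d", j)
    gene_entry[[gid]] <- add_entry(
      id = nid(), names = gid, etype = "gene",
      reaction_attr = if (j %in% unwired) character() else rid,
      graphics = kgml_graphics(label = sprintf("SYG%d", j),
                               bgcolor = "#BFFFBF", fgcolor = "#000000",
                               x = 10 * next_id, y = 80, width = 46,
                               height = 17, shape = "rectangle"))
  }
  manifest$unwired_enzymes <- lapply(unwired, function(j)
    list(entry = unname(gene_entry[[sprintf("syn:1%04d", j)]]),
         reaction = sprintf("rn:RT%04d", j)))

  manifest$duplicates <- list()
  for (k in seq_len(config$duplicates)) {
    gid <- sprintf("syn:1%04d", k)
    # the copy catalyzes the *next* reaction, as graphical copies do
    other <- sprintf("rn:RT%04d", if (nR > 1) (k %% nR) + 1L else 1L)
    did <- add_entry(
      id = nid(), names = gid, etype = "gene", reaction_attr = other,
      graphics = kgml_graphics(label = sprintf("SYG%d", k),
                               bgcolor = "#BFFFBF", fgcolor = "#000000",
                               x = 300 + 10 * k, y = 120, width = 46,
                               height = 17, shape = "rectangle"))
    manifest$duplicates[[length(manifest$duplicates) + 1L]] <-
      c(unname(gene_entry[[gid]]), did)
  }

  manifest$white_nodes <- integer()
  for (k in seq_len(config$white_nodes)) {
    wid <- add_entry(
      id = nid(), names = sprintf("ko:KT%04d", k), etype = "ortholog",
      graphics = kgml_graphics(label = sprintf("KT%04d", k),
                               bgcolor = "#FFFFFF", fgcolor = "#000000",
                               x = 400 + 10 * k, y = 160, width = 46,
                               height = 17, shape = "rectangle"))
    manifest$white_nodes <- c(manifest$white_nodes, wid)
  }

  manifest$maplinks <- integer()
  for (k in seq_len(config$maplinks)) {
    mid <- add_entry(
      id = nid(), names = sprintf("path:syn%05d", k), etype = "map",
      graphics = kgml_graphics(label = sprintf("synthetic map %d", k),
                               bgcolor = "#C0C0C0", fgcolor = "#000000",
                               x = 500 + 10 * k, y = 200, width = 90,
                               height = 25, shape = "roundrectangle"))
    manifest$maplinks <- c(manifest$maplinks, mid)
  }

  manifest$orphans <- integer()
  for (id in orphan_cpds)
    manifest$orphans <- c(manifest$orphans,
                          add_entry(id = nid(), names = id,
                                    etype = "compound"))

  manifest$groups <- integer()
  for (k in seq_len(config$groups)) {
    comp <- unname(gene_entry[c(sprintf("syn:1%04d", 1:2))])
    manifest$groups <- c(manifest$groups,
                         add_entry(id = nid(), names = character(),
                                   etype = "group", components = comp))
  }

  manifest$reaction_entries <- integer()
  for (k in seq_len(config$reaction_entries))
    manifest$reaction_entries <- c(
      manifest$reaction_entries,
      add_entry(id = nid(), names = sprintf("rn:RT%04d", 1L),
                etype = "reaction"))

  # --- relations ----------------------------------------------------------
  relations <- list()
  gene_eids <- unname(gene_entry)
  ngen <- length(gene_eids)
  manifest$relations <- list()
  ri <- 0L
  for (st in config$relation_subtypes) {
    ri <- ri + 1L
    src <- gene_eids[((ri - 1L) %% ngen) + 1L]
    tgt <- gene_eids[(ri %% ngen) + 1L]
    rtype <- if (st %in% c("expression", "repression")) "GErel" else "PPrel"
    relations[[length(relations) + 1L]] <- kgml_relation(
      entry1 = src, entry2 = tgt, rtype = rtype,
      subtypes = list(list(name = st,
                           value = unname(RELATION_SUBTYPE_VALUES[[st]]))))
    manifest$relations[[length(manifest$relations) + 1L]] <-
      list(subtype = st, entry1 = src, entry2 = tgt)
  }
  # white nodes hang off a relation so they are not orphans
  for (wid in manifest$white_nodes)
    relations[[length(relations) + 1L]] <- kgml_relation(
      entry1 = wid, entry2 = gene_eids[1], rtype = "PPrel",
      subtypes = list(list(name = "activation", value = "-->")))
  for (mid in manifest$maplinks)
    relations[[length(relations) + 1L]] <- kgml_relation(
      entry1 = gene_eids[1], entry2 = mid, rtype = "maplink",
      subtypes = list())
  for (eid in manifest$reaction_entries)
    relations[[length(relations) + 1L]] <- kgml_relation(
      entry1 = gene_eids[min(2, ngen)], entry2 = eid, rtype = "PCrel",
      subtypes = list(list(name = "activation", value = "-->")))
  manifest$compound_relations <- integer()
  for (k in seq_len(config$compound_relations)) {
    shared <- cpd_entry[[rx_subs[[sprintf("rn:RT%04d",
                                          ((k - 1L) %% nR) + 1L)]][[1]]$id]]
    relations[[length(relations) + 1L]] <- kgml_relation(
      entry1 = gene_eids[((k - 1L) %% ngen) + 1L],
      entry2 = gene_eids[(k %% ngen) + 1L], rtype = "ECrel",
      subtypes = list(list(name = "compound", value = as.character(shared))))
    manifest$compound_relations <- c(manifest$compound_relations,
                                     length(relations))
  }

  # --- KGML reactions -----------------------------------------------------
  xml_reactions <- list()
  in_bundle <- unlist(manifest$bundled)
  partner_of <- stats::setNames(
    vapply(manifest$bundled, `[[`, "", 2),
    vapply(manifest$bundled, `[[`, "", 1))
  part_refs <- function(ps, omit_id = NULL) {
    out <- list()
    for (p in ps) {
      if (!is.null(omit_id) && p$id == omit_id) next
      out[[length(out) + 1L]] <- kgml_participant(
        entry_id = cpd_entry[[p$id]], kegg_id = p$id,
        stoichiometry = p$coeff)
    }
    out
  }
  for (j in seq_len(nR)) {
    rid <- sprintf("rn:RT%04d", j)
    rec <- reactions[[rid]]
    omit <- NULL
    for (m in manifest$missing)
      if (m$reaction == rid) omit <- m$kegg_id
    ids <- rid
    if (rid %in% names(partner_of)) ids <- c(rid, partner_of[[rid]])
    xml_reactions[[length(xml_reactions) + 1L]] <- kgml_reaction(
      ids = ids, rtype = if (rec$reversible) "reversible" else "irreversible",
      substrates = part_refs(rx_subs[[rid]]),
      products = part_refs(rx_prod[[rid]], omit_id = omit))
  }

  doc <- kgml_pathway(name = "path:syn00001", org = "syn", number = "00001",
                      title = "synthetic fixture pathway",
                      entries = entries, relations = relations,
                      reactions = xml_reactions)
  doc <- rewire_modifiers(doc)

  manifest$counts <- list(entries = length(entries),
                          relations = length(relations),
                          reactions = length(xml_reactions),
                          reaction_ids = sum(lengths(
                            lapply(xml_reactions, function(r) r$ids))),
                          store_reactions = length(reactions),
                          store_compounds = length(compounds),
                          store_genes = length(genes))
  list(doc = doc, store = store, manifest = manifest)
}

#' A fixture configuration with no planted defects
#'
#' Every defect count zero; useful for identity/bijection properties.
#'
#' @param n_reactions Number of base reactions.
#' @param relation_subtypes Relation subtypes to plant (defect-free
#'   relations are still generated).
#' @return A [fixture_config()].
#' @export
clean_fixture_config <- function(n_reactions = 5,
                                 relation_subtypes =
                                   names(RELATION_SUBTYPE_VALUES)) {
  fixture_config(n_reactions = n_reactions, bundled = 0,
                 missing_participants = 0, duplicates = 0, white_nodes = 0,
                 maplinks = 0, orphans = 0, groups = 1, reaction_entries = 0,
                 relation_subtypes = relation_subtypes,
                 compound_relations = 0, glycan_aliases = 0,
                 missing_enzyme_links = 0, planted_imbalance = 0)
}

#' Write a generated fixture to disk
#'
#' Emits `pathway.xml` (KGML), the store files and `manifest.yaml` into
#' `dir`.
#'
#' @param fixture Result of [generate_fixture()].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(fixture, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_kgml(fixture$doc, file.path(dir, "pathway.xml"))
  write_store(fixture$store, file.path(dir, "store"))
  yaml::write_yaml(fixture$manifest, file.path(dir, "manifest.yaml"))
  invisible(dir)
}
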