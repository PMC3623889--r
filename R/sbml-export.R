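# SBML serialization: core model for the metabolic content, qualitative
# transitions (L3 qual package) for relations, groups package or HAS_PART
# annotations for complexes. Entry types map to SBO terms from the
# material-entity branch; reaction participants carry substrate/product or
# generic-reactant SBO terms depending on reversibility.

SBML_CORE_L3 <- "http://www.sbml.org/sbml/level3/version1/core"
SBML_CORE_L2 <- "http://www.sbml.org/sbml/level2/version4"
SBML_QUAL_NS <- "http://www.sbml.org/sbml/level3/version1/qual/version1"
SBML_GROUPS_NS <- "http://www.sbml.org/sbml/level3/version1/groups/version1"
RDF_NS <- "http://www.w3.org/1999/02/22-rdf-syntax-ns#"
BQBIOL_NS <- "http://biomodels.net/biology-qualifiers/"

# entry type -> SBO accession for the created species
ENTRY_SBO <- c(compound = 247L, enzyme = 252L, gene = 252L, ortholog = 252L,
               group = 253L, map = 552L)

# relation subtype -> (SBO, MI, GO) accessions and interaction label
SUBTYPE_VOCAB <- list(
  "activation" = list(sbo = 170L, mi = NA_integer_, go = NA_integer_,
                      label = "stimulation"),
  "inhibition" = list(sbo = 169L, mi = NA_integer_, go = NA_integer_,
                      label = "inhibition"),
  "expression" = list(sbo = 170L, mi = NA_integer_, go = 10467L,
                      label = "gene expression"),
  "repression" = list(sbo = 169L, mi = NA_integer_, go = NA_integer_,
                      label = "gene repression"),
  "indirect effect" = list(sbo = 344L, mi = NA_integer_, go = NA_integer_,
                           label = "molecular interaction"),
  "state change" = list(sbo = 168L, mi = NA_integer_, go = NA_integer_,
                        label = "control"),
  "binding/association" = list(sbo = 177L, mi = 914L, go = 5488L,
                               label = "non-covalent binding"),
  "dissociation" = list(sbo = 180L, mi = NA_integer_, go = NA_integer_,
                        label = "dissociation"),
  "missing interaction" = list(sbo = 396L, mi = NA_integer_,
                               go = NA_integer_, label = "uncertain process"),
  "phosphorylation" = list(sbo = 216L, mi = 217L, go = 16310L,
                           label = "phosphorylation"),
  "dephosphorylation" = list(sbo = 330L, mi = 203L, go = 16311L,
                             label = "dephosphorylation"),
  "glycosylation" = list(sbo = 217L, mi = 559L, go = 70085L,
                         label = "glycosylation"),
  "ubiquitination" = list(sbo = 224L, mi = 220L, go = 16567L,
                          label = "ubiquitination"),
  "methylation" = list(sbo = 214L, mi = 213L, go = 32259L,
                       label = "methylation"))

# most specific subtype wins when a relation carries several
SUBTYPE_PRIORITY <- c("phosphorylation", "dephosphorylation", "glycosylation",
                      "ubiquitination", "methylation", "binding/association",
                      "dissociation", "expression", "repression",
                      "activation", "inhibition", "state change",
                      "missing interaction", "indirect effect")

# small organism-code -> NCBI taxonomy map for model-level annotation
TAXON_MAP <- c(hsa = 9606L, mmu = 10090L, rno = 10116L, dme = 7227L,
               cel = 6239L, sce = 559292L, eco = 511145L)

#' SBO accession for a KGML entry type
#'
#' Species-forming entry types map into the SBO material-entity branch:
#' compound 247 (simple chemical), enzyme/gene/ortholog 252 (polypeptide
#' chain), group 253 (non-covalent complex), map 552 (reference
#' annotation). Types `reaction` and `other` form no species in SBML core
#' and return `NA`.
#'
#' @param etype Entry type string.
#' @return Integer SBO accession, or `NA` for the no-species types.
#' @export
#' @examples
#' sbo_for_entry_type("compound")
sbo_for_entry_type <- function(etype) {
  if (etype %in% names(ENTRY_SBO)) ENTRY_SBO[[etype]] else NA_integer_
}

sbo_str <- function(acc) sprintf("SBO:%07d", acc)

#' Sanitize a raw identifier into an SBML id
#'
#' Colons, spaces, dots, dashes and every other non-word character become
#' underscores; identifiers starting with a digit gain a leading
#' underscore. Injectivity within a document is handled by the translator
#' via numeric suffixing on collisions.
#'
#' @param raw Non-empty string.
#' @return A string matching the SBML identifier grammar.
#' @export
#' @examples
#' sanitize_sid("hsa:5594")
#' sanitize_sid("3dmet")
sanitize_sid <- function(raw) {
  if (is.null(raw) || is.na(raw) || !nzchar(raw))
    stop("sanitize_sid: empty identifier", call. = FALSE)
  s <- gsub("[^A-Za-z0-9_]", "_", raw)
  if (grepl("^[0-9]", s)) s <- paste0("_", s)
  s
}

# collision-proof sid allocator
new_sid_pool <- function() {
  used <- new.env(parent = emptyenv())
  function(raw) {
    s <- sanitize_sid(raw)
    if (!exists(s, envir = used)) {
      assign(s, TRUE, envir = used)
      return(s)
    }
    k <- 2L
    while (exists(paste0(s, "_", k), envir = used)) k <- k + 1L
    s <- paste0(s, "_", k)
    assign(s, TRUE, envir = used)
    s
  }
}

#' SBML serialization target
#'
#' @param level_version `"L3V1"` or `"L2V4"`.
#' @param use_qual Emit the qualitative-models package (L3 only): one
#'   transition per relation.
#' @param use_groups Emit the groups package for group entries (L3 only);
#'   otherwise complexes are species with SBO 253 and a HAS_PART term.
#' @return A list of class `sbml_target`.
#' @export
sbml_target <- function(level_version = c("L3V1", "L2V4"), use_qual = FALSE,
                        use_groups = FALSE) {
  level_version <- match.arg(level_version)
  if (use_qual && level_version != "L3V1")
    stop("the qualitative-models package requires SBML Level 3", call. = FALSE)
  if (use_groups && level_version != "L3V1")
    stop("the groups package requires SBML Level 3", call. = FALSE)
  structure(list(level_version = level_version, use_qual = use_qual,
                 use_groups = use_groups),
            class = "sbml_target")
}

# ---- annotation helpers -----------------------------------------------------

QUALIFIER_ELEMENT <- c(IS = "bqbiol:is", HAS_PART = "bqbiol:hasPart",
                       IS_ENCODED_BY = "bqbiol:isEncodedBy",
                       IS_DESCRIBED_BY = "bqbiol:isDescribedBy",
                       HAS_VERSION = "bqbiol:hasVersion",
                       OCCURS_IN = "bqbiol:occursIn")

add_cv_annotation <- function(node, metaid, terms) {
  if (length(terms) == 0L) return(invisible(NULL))
  esc <- function(x) gsub("\"", "&quot;", gsub("&", "&amp;", x, fixed = TRUE))
  body <- vapply(terms, function(t) {
    paste0("<", QUALIFIER_ELEMENT[[t$qualifier]], "><rdf:Bag>",
           paste0("<rdf:li rdf:resource=\"", esc(t$urns), "\"/>",
                  collapse = ""),
           "</rdf:Bag></", QUALIFIER_ELEMENT[[t$qualifier]], ">")
  }, "")
  frag <- xml2::read_xml(paste0(
    "<rdf:RDF xmlns:rdf=\"", RDF_NS, "\" xmlns:bqbiol=\"", BQBIOL_NS, "\">",
    "<rdf:Description rdf:about=\"#", metaid, "\">",
    paste(body, collapse = ""),
    "</rdf:Description></rdf:RDF>"))
  ann <- xml2::xml_add_child(node, "annotation")
  xml2::xml_add_child(ann, frag)
  invisible(NULL)
}

add_notes <- function(node, nb, title = NULL) {
  notes <- xml2::xml_add_child(node, "notes")
  body <- xml2::read_xml(note_xhtml_body(nb, title))
  xml2::xml_add_child(notes, body)
  invisible(NULL)
}

# primary vocabulary for a relation: most specific subtype first
relation_vocab <- function(rel) {
  nms <- vapply(rel$subtypes, function(s) s$name, "")
  nms <- nms[nms %in% names(SUBTYPE_VOCAB)]
  if (length(nms) == 0L) return(NULL)
  ord <- order(match(nms, SUBTYPE_PRIORITY))
  list(primary = SUBTYPE_VOCAB[[nms[ord[1]]]],
       primary_name = nms[ord[1]],
       secondary = SUBTYPE_VOCAB[nms[ord[-1]]])
}

# ---- translation ------------------------------------------------------------

#' Translate a preprocessed pathway document to SBML
#'
#' Emits one species per surviving non-reaction entry (SBO per entry type),
#' one SBML reaction per KGML reaction (substrate references SBO 15 and
#' product references SBO 11 when irreversible; a uniform generic-reactant
#' SBO 10 on every participant when reversible), enzymes as modifier
#' references, and — with `use_qual` — one qualitative transition per
#' relation, carrying the subtype's SBO term and GO CV term. All elements
#' live in a single default compartment (KEGG encodes no
#' compartmentalization). The output is byte-deterministic and passes a
#' structural self-check (unique ids, resolvable references, SBO terms
#' present).
#'
#' @param doc A preprocessed [kgml_pathway()].
#' @param store A `resource_store`.
#' @param target A [sbml_target()].
#' @return An `xml2` document.
#' @export
translate_sbml <- function(doc, store, target = sbml_target()) {
  l3 <- target$level_version == "L3V1"
  if (!l3 && length(doc$relations) > 0L && !target$use_qual)
    warning("relations cannot be encoded in SBML core; ",
            "they are omitted from the L2V4 document", call. = FALSE)

  root_attrs <- c(
    list(xmlns = if (l3) SBML_CORE_L3 else SBML_CORE_L2,
         level = if (l3) "3" else "2", version = if (l3) "1" else "4"),
    if (l3 && target$use_qual)
      list("xmlns:qual" = SBML_QUAL_NS, "qual:required" = "false"),
    if (l3 && target$use_groups)
      list("xmlns:groups" = SBML_GROUPS_NS, "groups:required" = "false"))
  x <- do.call(xml2::xml_new_root,
               c(list("sbml"), lapply(root_attrs, as.character)))

  sid <- new_sid_pool()
  model_id <- sid(doc$name)
  model <- xml2::xml_add_child(x, "model")
  set_attrs(model, list(id = model_id, metaid = paste0("meta_", model_id),
                        name = doc$title))
  model_terms <- list(cv_term("IS", kegg_urn(doc$name)))
  if (doc$org %in% names(TAXON_MAP))
    model_terms[[length(model_terms) + 1L]] <-
      cv_term("OCCURS_IN", miriam_urn("taxonomy", TAXON_MAP[[doc$org]]))
  add_cv_annotation(model, paste0("meta_", model_id), model_terms)

  comp_list <- xml2::xml_add_child(model, "listOfCompartments")
  comp <- xml2::xml_add_child(comp_list, "compartment")
  set_attrs(comp, c(list(id = "default", name = "default compartment"),
                    if (l3) list(constant = "true") else list(size = "1")))

  # species for every surviving entry except reaction-type ones; group
  # entries become group objects instead when the groups package is on
  species_sid <- character()     # entry id -> sid
  species_entries <- Filter(function(e) !e$etype %in% c("reaction", "other"),
                            doc$entries)
  group_entries <- Filter(function(e) e$etype == "group", species_entries)
  emit_group_objects <- l3 && target$use_groups
  if (emit_group_objects)
    species_entries <- Filter(function(e) e$etype != "group", species_entries)

  sp_list <- xml2::xml_add_child(model, "listOfSpecies")
  for (e in species_entries) {
    raw <- if (length(e$names)) e$names[1] else paste0("entry", e$id)
    s <- sid(raw)
    species_sid[[as.character(e$id)]] <- s
    sp <- xml2::xml_add_child(sp_list, "species")
    nb <- notes_for(e, store)
    label <- if (!is.null(e$graphics) && !is.na(e$graphics$label))
      e$graphics$label else raw
    set_attrs(sp, c(
      list(id = s, metaid = paste0("meta_", s), name = label,
           compartment = "default",
           sboTerm = sbo_str(sbo_for_entry_type(e$etype))),
      if (l3) list(hasOnlySubstanceUnits = "false",
                   boundaryCondition = "false", constant = "false")))
    add_notes(sp, nb, title = label)
    terms <- cv_terms_for_entry(e, store, doc)
    if (e$etype == "group" && length(terms) == 0L)
      stop("export error: group entry ", e$id, " has no resolvable members",
           call. = FALSE)
    add_cv_annotation(sp, paste0("meta_", s), terms)
  }

  # reactions
  rx_list <- xml2::xml_add_child(model, "listOfReactions")
  for (rx in doc$reactions) {
    if (length(rx$ids) != 1L)
      stop("export error: bundled reaction ", paste(rx$ids, collapse = " "),
           " (run unbundle_reactions first)", call. = FALSE)
    r <- sid(rx$ids)
    rn <- xml2::xml_add_child(rx_list, "reaction")
    reversible <- rx$rtype == "reversible"
    set_attrs(rn, c(list(id = r, metaid = paste0("meta_", r),
                         reversible = if (reversible) "true" else "false",
                         sboTerm = sbo_str(176L)),
                    if (l3) NULL else list(fast = "false")))
    bal <- reaction_atom_diff(rx, store)
    add_notes(rn, notes_for(rx, store, balance = bal), title = rx$ids)
    add_cv_annotation(rn, paste0("meta_", r),
                      list(cv_term("IS", kegg_urn(rx$ids))))
    part_node <- function(parent_name, parts, part_sbo) {
      if (length(parts) == 0L) return(invisible(NULL))
      ln <- xml2::xml_add_child(rn, parent_name)
      for (p in parts) {
        s <- species_sid[[as.character(p$entry_id)]]
        if (is.null(s) || is.na(s))
          stop("export integrity error: reaction ", rx$ids,
               " participant entry ", p$entry_id, " has no species",
               call. = FALSE)
        pr <- xml2::xml_add_child(ln, "speciesReference")
        set_attrs(pr, c(list(species = s,
                             stoichiometry = num_attr(p$stoichiometry),
                             sboTerm = sbo_str(part_sbo)),
                        if (l3) list(constant = "true")))
      }
    }
    sub_sbo <- if (reversible) 10L else 15L
    prod_sbo <- if (reversible) 10L else 11L
    part_node("listOfReactants", rx$substrates, sub_sbo)
    part_node("listOfProducts", rx$products, prod_sbo)
    if (length(rx$modifiers)) {
      ln <- xml2::xml_add_child(rn, "listOfModifiers")
      for (m in rx$modifiers) {
        s <- species_sid[[as.character(m)]]
        if (is.null(s) || is.na(s)) next   # modifier pruned away
        mr <- xml2::xml_add_child(ln, "modifierSpeciesReference")
        set_attrs(mr, list(species = s, sboTerm = sbo_str(13L)))
      }
    }
  }

  # groups package
  if (emit_group_objects && length(group_entries)) {
    gl <- xml2::xml_add_child(model, "groups:listOfGroups")
    for (e in group_entries) {
      g <- sid(paste0("group", e$id))
      gn <- xml2::xml_add_child(gl, "groups:group")
      set_attrs(gn, list("groups:id" = g, "groups:kind" = "partonomy",
                         sboTerm = sbo_str(253L)))
      ml <- xml2::xml_add_child(gn, "groups:listOfMembers")
      for (cid in e$components) {
        s <- species_sid[[as.character(cid)]]
        if (is.null(s) || is.na(s)) {
          warning("group ", e$id, " member ", cid,
                  " was removed by preprocessing", call. = FALSE)
          next
        }
        mn <- xml2::xml_add_child(ml, "groups:member")
        set_attrs(mn, list("groups:idRef" = s))
      }
    }
  }

  # qualitative model
  if (l3 && target$use_qual) {
    qs_sid <- character()
    ql <- xml2::xml_add_child(model, "qual:listOfQualitativeSpecies")
    for (e in doc$entries) {
      # reaction-type entries need qualitative species too: transitions may
      # target them
      raw <- if (length(e$names)) e$names[1] else paste0("entry", e$id)
      qsid <- sid(paste0(sanitize_sid(raw), "_q"))
      qs_sid[[as.character(e$id)]] <- qsid
      qn <- xml2::xml_add_child(ql, "qual:qualitativeSpecies")
      set_attrs(qn, list("qual:id" = qsid,
                         metaid = paste0("meta_", qsid),
                         "qual:compartment" = "default",
                         "qual:constant" = "false",
                         sboTerm = if (e$etype == "reaction") sbo_str(375L)
                         else if (e$etype == "other") sbo_str(285L)
                         else sbo_str(sbo_for_entry_type(e$etype))))
      terms <- if (e$etype == "reaction")
        lapply(e$names, function(nm) cv_term("IS", kegg_urn(nm)))
      else cv_terms_for_entry(e, store, doc)
      add_cv_annotation(qn, paste0("meta_", qsid), terms)
    }
    tl <- xml2::xml_add_child(model, "qual:listOfTransitions")
    ti <- 0L
    for (rel in doc$relations) {
      tr <- relation_to_transition(rel, doc, target, qs_sid, sid)
      if (is.null(tr)) next
      ti <- ti + 1L
      tn <- xml2::xml_add_child(tl, "qual:transition")
      set_attrs(tn, list("qual:id" = tr$id,
                         metaid = paste0("meta_", tr$id),
                         sboTerm = tr$sbo))
      if (length(tr$cv_terms))
        add_cv_annotation(tn, paste0("meta_", tr$id), tr$cv_terms)
      inl <- xml2::xml_add_child(tn, "qual:listOfInputs")
      inn <- xml2::xml_add_child(inl, "qual:input")
      set_attrs(inn, c(list("qual:id" = paste0(tr$id, "_in"),
                            "qual:qualitativeSpecies" = tr$input,
                            "qual:transitionEffect" = "none"),
                       if (!is.na(tr$sign)) list("qual:sign" = tr$sign)))
      outl <- xml2::xml_add_child(tn, "qual:listOfOutputs")
      outn <- xml2::xml_add_child(outl, "qual:output")
      set_attrs(outn, list("qual:id" = paste0(tr$id, "_out"),
                           "qual:qualitativeSpecies" = tr$output,
                           "qual:transitionEffect" = "assignmentLevel"))
    }
  }

  v <- validate_sbml_structure(x)
  if (nrow(v))
    stop("SBML structural self-validation failed:\n",
         paste(v$message, collapse = "\n"), call. = FALSE)
  x
}

#' Build the transition record for one relation
#'
#' One qualitative transition per relation: input is the source entry's
#' qualitative species, output the target's. The transition carries the
#' subtype's SBO term (the most specific modification subtype wins when
#' several are present; the others become extra CV terms) and the GO term
#' the subtype maps to, when one exists. No function terms are emitted —
#' KEGG carries no qualitative logic to fill them with.
#'
#' @param rel A [kgml_relation()].
#' @param doc The containing document.
#' @param target An [sbml_target()] with `use_qual = TRUE`.
#' @param qs_sid Named map entry id -> qualitative species id.
#' @param sid Sid allocator (from the enclosing translation).
#' @return A list (`id`, `input`, `output`, `sbo`, `sign`, `cv_terms`) or
#'   `NULL` for relations without a mappable subtype (e.g. pure `compound`
#'   relations or maplinks).
#' @keywords internal
relation_to_transition <- function(rel, doc, target, qs_sid, sid) {
  if (!isTRUE(target$use_qual))
    stop("relations cannot be encoded without the qual package", call. = FALSE)
  voc <- relation_vocab(rel)
  if (is.null(voc)) return(NULL)
  input <- qs_sid[[as.character(rel$entry1)]]
  output <- qs_sid[[as.character(rel$entry2)]]
  if (is.null(input) || is.null(output))
    stop("export integrity error: relation endpoint without qualitative ",
         "species (", rel$entry1, " -> ", rel$entry2, ")", call. = FALSE)
  cv <- list()
  if (!is.na(voc$primary$go))
    cv[[length(cv) + 1L]] <- cv_term(
      "IS", miriam_urn("go", sprintf("GO:%07d", voc$primary$go)))
  for (sec in voc$secondary)
    cv[[length(cv) + 1L]] <- cv_term(
      "IS", miriam_urn("biomodels.sbo", sbo_str(sec$sbo)))
  sign <- if (voc$primary_name %in% c("activation", "expression"))
    "positive"
  else if (voc$primary_name %in% c("inhibition", "repression"))
    "negative"
  else NA_character_
  list(id = sid(paste0("tr_", sanitize_sid(voc$primary_name), "_",
                       rel$entry1, "_", rel$entry2)),
       input = input, output = output, sbo = sbo_str(voc$primary$sbo),
       sign = sign, cv_terms = cv)
}

#' Structural self-validation of a generated SBML document
#'
#' Checks id uniqueness, resolvability of species references (core and
#' qual) and presence of SBO terms on species, participant references and
#' transitions.
#'
#' @param x An `xml2` SBML document.
#' @return A tibble of findings (empty when sound).
#' @export
validate_sbml_structure <- function(x) {
  ns <- c(s = xml2::xml_ns(x)[["d1"]], qual = SBML_QUAL_NS)
  msgs <- character()
  # attribute lookup tolerant of namespace prefixes
  attr_of <- function(nodes, name) vapply(nodes, function(n) {
    a <- xml2::xml_attrs(n)
    hit <- names(a)[sub("^.*:", "", names(a)) == name]
    if (length(hit)) a[[hit[1]]] else NA_character_
  }, "")
  sp <- xml2::xml_find_all(x, ".//s:species", ns)
  sids <- xml2::xml_attr(sp, "id")
  qs <- xml2::xml_find_all(x, ".//qual:qualitativeSpecies", ns)
  qids <- attr_of(qs, "id")
  all_ids <- c(sids, qids,
               xml2::xml_attr(xml2::xml_find_all(x, ".//s:reaction", ns), "id"))
  dup <- unique(all_ids[duplicated(all_ids)])
  if (length(dup))
    msgs <- c(msgs, paste("duplicate id:", dup))
  for (n in xml2::xml_find_all(x, ".//s:speciesReference", ns))
    if (!xml2::xml_attr(n, "species") %in% sids)
      msgs <- c(msgs, paste("unresolvable species reference:",
                            xml2::xml_attr(n, "species")))
  for (n in xml2::xml_find_all(x, ".//s:modifierSpeciesReference", ns))
    if (!xml2::xml_attr(n, "species") %in% sids)
      msgs <- c(msgs, paste("unresolvable modifier reference:",
                            xml2::xml_attr(n, "species")))
  for (n in c(sp, xml2::xml_find_all(x, ".//s:speciesReference", ns),
              xml2::xml_find_all(x, ".//qual:transition", ns)))
    if (is.na(xml2::xml_attr(n, "sboTerm")))
      msgs <- c(msgs, paste("missing sboTerm on", xml2::xml_name(n)))
  io <- xml2::xml_find_all(x, ".//qual:input | .//qual:output", ns)
  for (ref in attr_of(io, "qualitativeSpecies"))
    if (!ref %in% qids)
      msgs <- c(msgs, paste("unresolvable qualitativeSpecies reference:", ref))
  if (length(msgs) == 0L)
    return(tibble::tibble(message = character()))
  tibble::tibble(message = msgs)
}

#' Write an SBML document to a file
#'
#' @param x An `xml2` document from [translate_sbml()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sbml <- function(x, path) {
  xml2::write_xml(x, path)
  invisible(path)
}
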