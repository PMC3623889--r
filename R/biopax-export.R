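# BioPAX (Levels 2 and 3) serialization as OWL/RDF-XML. Entities are built
# in a format-neutral intermediate (lists of elements with literal and
# resource properties) so the relation translation logic is testable
# without XML, then serialized with xml2. RDF identifiers are stable and
# derived from sanitized KEGG ids so diffs between runs are meaningful.

BP3_NS <- "http://www.biopax.org/release/biopax-level3.owl#"
BP2_NS <- "http://www.biopax.org/release/biopax-level2.owl#"
OWL_NS <- "http://www.w3.org/2002/07/owl#"
XSD_STRING <- "http://www.w3.org/2001/XMLSchema#string"
XSD_FLOAT <- "http://www.w3.org/2001/XMLSchema#float"

#' BioPAX serialization target
#'
#' @param level 2 or 3. Level 3 adds entity references, TemplateReactions
#'   for expression relations, ModificationFeatures and explicit
#'   Stoichiometry objects; Level 2 uses the corresponding fallbacks.
#' @return A list of class `biopax_target`.
#' @export
biopax_target <- function(level = 3) {
  if (!level %in% c(2, 3))
    stop("BioPAX level must be 2 or 3", call. = FALSE)
  structure(list(level = as.integer(level)), class = "biopax_target")
}

#' BioPAX element kind for a KGML entry type
#'
#' compound -> small molecule, enzyme/gene/ortholog -> protein,
#' group -> complex, map -> pathway (level-appropriate casing; Level 2
#' class names are lowerCamelCase). Entry type `reaction` signals an
#' interaction and forms no physical entity.
#'
#' @param etype Entry type string.
#' @param level 2 or 3.
#' @return Class-name string, or `NA` for the interaction signal.
#' @export
#' @examples
#' class_for_entry_type("compound", 3)
class_for_entry_type <- function(etype, level = 3) {
  base <- switch(etype,
                 compound = "SmallMolecule",
                 enzyme = , gene = , ortholog = "Protein",
                 group = "Complex",
                 map = "Pathway",
                 other = "PhysicalEntity",
                 reaction = return(NA_character_),
                 stop("unknown entry type '", etype, "'", call. = FALSE))
  if (level == 2) paste0(tolower(substr(base, 1, 1)), substr(base, 2, 1e6))
  else base
}

#' Ontology vocabulary for a KGML relation subtype
#'
#' Exact accessions per the published subtype grid: an SBO term always;
#' MI and GO terms where the subtype has them. MOD accessions are not part
#' of the grid, so `mod` is always `NA` and Level 3 modification features
#' carry the human-readable modification term only.
#'
#' @param subtype Relation subtype name.
#' @param level 2 or 3 (the accessions are level-independent; the element
#'   kinds differ).
#' @return A list (`sbo`, `mi`, `go`, `mod`, `label`, `element`).
#' @export
#' @examples
#' vocabulary_terms("binding/association")
vocabulary_terms <- function(subtype, level = 3) {
  v <- SUBTYPE_VOCAB[[subtype]]
  if (is.null(v))
    stop("vocabulary error: unknown relation subtype '", subtype, "'",
         call. = FALSE)
  element <- switch(subtype,
                    "expression" = , "repression" =
                      if (level == 3) "TemplateReaction"
                      else "conversion+control",
                    "binding/association" = , "dissociation" =
                      "ComplexAssembly",
                    "missing interaction" =
                      if (level == 3) "MolecularInteraction"
                      else "physicalInteraction",
                    "indirect effect" = , "state change" = "Conversion",
                    "conversion+control")
  list(sbo = v$sbo, mi = v$mi, go = v$go, mod = NA_integer_,
       label = v$label, element = element)
}

# ---- intermediate element model --------------------------------------------

bpx_el <- function(kind, id, props = list()) {
  list(kind = kind, id = id, props = props)
}
lit <- function(name, value, datatype = XSD_STRING)
  list(name = name, value = as.character(value), type = "literal",
       datatype = datatype)
res <- function(name, id) list(name = name, value = id, type = "resource")

# builder environment carrying the element list and id registry
new_bpx_builder <- function(level) {
  b <- new.env(parent = emptyenv())
  b$level <- level
  b$elements <- list()
  b$ids <- character()
  b$add <- function(kind, id, props = list()) {
    if (id %in% b$ids)
      stop("duplicate BioPAX rdf:ID '", id, "'", call. = FALSE)
    b$ids <- c(b$ids, id)
    b$elements[[id]] <- bpx_el(kind, id, props)
    id
  }
  b$append_prop <- function(id, prop) {
    el <- b$elements[[id]]
    el$props[[length(el$props) + 1L]] <- prop
    b$elements[[id]] <- el
  }
  b$has <- function(id) id %in% b$ids
  b
}

# level-aware property names
bp_prop <- function(level, l3name) {
  if (level == 3) return(l3name)
  switch(l3name,
         displayName = "SHORT-NAME", name = "NAME", comment = "COMMENT",
         xref = "XREF", left = "LEFT", right = "RIGHT",
         participant = "PARTICIPANTS", controller = "CONTROLLER",
         controlled = "CONTROLLED", controlType = "CONTROL-TYPE",
         eCNumber = "EC-NUMBER", organism = "ORGANISM",
         component = "COMPONENTS", pathwayComponent = "PATHWAY-COMPONENTS",
         interactionType = "INTERACTION-TYPE",
         chemicalFormula = "CHEMICAL-FORMULA",
         molecularWeight = "MOLECULAR-WEIGHT",
         term = "TERM", db = "DB", id = "ID",
         conversionDirection = "DIRECTION",
         l3name)
}

bp_kind <- function(level, l3kind) {
  if (level == 3) return(l3kind)
  map <- c(SmallMolecule = "smallMolecule", Protein = "protein",
           Complex = "complex", Pathway = "pathway",
           PhysicalEntity = "physicalEntity",
           BiochemicalReaction = "biochemicalReaction",
           Catalysis = "catalysis", Control = "control",
           Conversion = "conversion", ComplexAssembly = "complexAssembly",
           MolecularInteraction = "physicalInteraction",
           UnificationXref = "unificationXref",
           RelationshipXref = "relationshipXref",
           InteractionVocabulary = "openControlledVocabulary",
           BioSource = "bioSource")
  if (l3kind %in% names(map)) map[[l3kind]] else l3kind
}

# xref object (unification for KEGG/identity, relationship otherwise)
add_xref <- function(b, db, id, unification = TRUE) {
  xid <- paste0("xref_", sanitize_sid(paste0(db, "_", id)))
  if (!b$has(xid)) {
    kind <- bp_kind(b$level, if (unification) "UnificationXref"
                    else "RelationshipXref")
    b$add(kind, xid, list(lit(bp_prop(b$level, "db"), db),
                          lit(bp_prop(b$level, "id"), id)))
  }
  xid
}

add_kegg_xrefs <- function(b, id, names, store, etype) {
  props <- list()
  for (nm in names) {
    kc <- kegg_id_collection(nm)
    props[[length(props) + 1L]] <-
      res(bp_prop(b$level, "xref"), add_xref(b, kc$collection, kc$id))
    xr <- xref_urns_for_id(nm, store, etype)
    for (coll in names(xr)) {
      bare <- sub("^urn:miriam:[^:]+:", "", xr[[coll]])
      bare <- vapply(bare, utils::URLdecode, "", USE.NAMES = FALSE)
      for (v in bare)
        props[[length(props) + 1L]] <-
          res(bp_prop(b$level, "xref"),
              add_xref(b, coll, v, unification = FALSE))
    }
  }
  props
}

# interaction vocabulary object for a subtype; returns element id
add_interaction_vocab <- function(b, subtype) {
  voc <- vocabulary_terms(subtype, b$level)
  vid <- paste0("iv_", sanitize_sid(subtype))
  if (b$has(vid)) return(vid)
  props <- list(lit(bp_prop(b$level, "term"), voc$label),
                res(bp_prop(b$level, "xref"),
                    add_xref(b, "sbo", sbo_str(voc$sbo))))
  if (!is.na(voc$mi))
    props[[length(props) + 1L]] <-
      res(bp_prop(b$level, "xref"),
          add_xref(b, "mi", sprintf("MI:%04d", voc$mi)))
  if (!is.na(voc$go))
    props[[length(props) + 1L]] <-
      res(bp_prop(b$level, "xref"),
          add_xref(b, "go", sprintf("GO:%07d", voc$go)))
  b$add(bp_kind(b$level, "InteractionVocabulary"), vid, props)
  vid
}

# ---- entity construction ----------------------------------------------------

entity_id_for <- function(e) {
  raw <- if (length(e$names)) e$names[1] else paste0("entry", e$id)
  paste0("ent_", sanitize_sid(raw), "_", e$id)
}

#' Create the BioPAX physical entity for one entry
#'
#' One element per (merged) entry. Complexes reference their component
#' elements; small molecules carry molecular weight and chemical formula in
#' the dedicated BioPAX fields; every element gets unification xrefs to its
#' KEGG identifiers and relationship xrefs from the store record. On
#' Level 3 a matching entity reference is created for proteins and small
#' molecules.
#'
#' @param entry A [kgml_entry()].
#' @param store A `resource_store`.
#' @param target A [biopax_target()].
#' @param builder Internal builder (created by the translator); exposed for
#'   testing.
#' @param doc Containing document (group component resolution).
#' @return The element id, invisibly.
#' @export
entry_to_element <- function(entry, store, target, builder = NULL,
                             doc = NULL) {
  b <- if (is.null(builder)) new_bpx_builder(target$level) else builder
  level <- b$level
  kind <- class_for_entry_type(entry$etype, level)
  if (is.na(kind))
    stop("entry of type 'reaction' forms an interaction, not an entity",
         call. = FALSE)
  eid <- entity_id_for(entry)
  if (b$has(eid)) return(invisible(eid))
  label <- if (!is.null(entry$graphics) && !is.na(entry$graphics$label))
    entry$graphics$label
  else if (length(entry$names)) entry$names[1]
  else paste0("entry ", entry$id)
  props <- list(lit(bp_prop(level, "displayName"), label))
  nb <- notes_for(entry, store)
  if (!is.na(nb$description))
    props[[length(props) + 1L]] <- lit(bp_prop(level, "comment"),
                                       nb$description)
  for (syn in nb$synonyms)
    props[[length(props) + 1L]] <- lit(bp_prop(level, "name"), syn)
  props <- c(props, add_kegg_xrefs(b, eid, entry$names, store, entry$etype))

  if (entry$etype == "group") {
    if (length(entry$components) == 0L)
      stop("export error: group entry ", entry$id, " has no components",
           call. = FALSE)
    for (cid in entry$components) {
      ce <- if (!is.null(doc)) get_entry(doc, cid) else NULL
      if (is.null(ce))
        stop("export error: dangling complex component ", cid, call. = FALSE)
      mid <- entry_to_element(ce, store, target, b, doc)
      props[[length(props) + 1L]] <-
        res(bp_prop(level, "component"), mid)
    }
  }

  if (entry$etype == "compound") {
    if (level == 3) {
      rid <- paste0("ref_", eid)
      rprops <- list(lit("displayName", label))
      if (!is.na(nb$formula))
        rprops[[length(rprops) + 1L]] <- lit("chemicalFormula", nb$formula)
      if (!is.na(nb$mol_weight))
        rprops[[length(rprops) + 1L]] <- lit("molecularWeight",
                                             format(nb$mol_weight),
                                             XSD_FLOAT)
      b$add("SmallMoleculeReference", rid, rprops)
      props[[length(props) + 1L]] <- res("entityReference", rid)
    } else {
      if (!is.na(nb$formula))
        props[[length(props) + 1L]] <- lit(bp_prop(2, "chemicalFormula"),
                                           nb$formula)
      if (!is.na(nb$mol_weight))
        props[[length(props) + 1L]] <- lit(bp_prop(2, "molecularWeight"),
                                           format(nb$mol_weight), XSD_FLOAT)
    }
  }
  if (entry$etype %in% c("gene", "enzyme", "ortholog") && level == 3) {
    rid <- paste0("ref_", eid)
    b$add("ProteinReference", rid, list(lit("displayName", label)))
    props[[length(props) + 1L]] <- res("entityReference", rid)
  }
  b$add(kind, eid, props)
  invisible(eid)
}

# L2 participants go through physicalEntityParticipant wrappers carrying
# the stoichiometric coefficient; L3 uses Stoichiometry objects
participant_ref <- function(b, entity_id, stoich, ctx) {
  if (b$level == 3) return(entity_id)
  pid <- paste0("pep_", ctx, "_", entity_id)
  if (!b$has(pid))
    b$add("physicalEntityParticipant", pid,
          list(res("PHYSICAL-ENTITY", entity_id),
               lit("STOICHIOMETRIC-COEFFICIENT", num_attr(stoich),
                   "http://www.w3.org/2001/XMLSchema#double")))
  pid
}

# ---- reactions and relations -----------------------------------------------

#' Translate one reaction to BioPAX interactions
#'
#' One BiochemicalReaction per reaction with per-participant stoichiometry
#' (explicit Stoichiometry objects on Level 3, participant-level
#' coefficients on Level 2), direction and EC numbers, plus one Catalysis
#' wiring the enzymes (Controller) to the reaction (Controlled) when
#' modifiers exist. The equation, definition and the full atom-balance
#' report are attached as comments.
#'
#' @param rx A completed [kgml_reaction()].
#' @param doc Containing [kgml_pathway()].
#' @param store A `resource_store`.
#' @param target A [biopax_target()].
#' @param builder Internal builder; exposed for testing.
#' @param entity_map Named map entry id -> element id.
#' @return Character vector of created interaction ids (reaction first).
#' @export
reaction_to_biopax <- function(rx, doc, store, target, builder = NULL,
                               entity_map = NULL) {
  b <- if (is.null(builder)) new_bpx_builder(target$level) else builder
  level <- b$level
  if (length(rx$ids) != 1L)
    stop("export error: bundled reaction (run unbundle_reactions first)",
         call. = FALSE)
  rid <- paste0("rxn_", sanitize_sid(rx$ids))
  bal <- reaction_atom_diff(rx, store)
  rec <- store$reactions[[rx$ids]]
  props <- list(lit(bp_prop(level, "displayName"), rx$ids))
  if (!is.null(rec) && nzchar(rec$definition))
    props[[length(props) + 1L]] <- lit(bp_prop(level, "comment"),
                                       rec$definition)
  if (!is.null(rec))
    props[[length(props) + 1L]] <- lit(bp_prop(level, "comment"),
                                       paste0("equation: ", rec$equation))
  props[[length(props) + 1L]] <- lit(bp_prop(level, "comment"),
                                     format_balance_report(bal))
  props[[length(props) + 1L]] <-
    lit(bp_prop(level, "conversionDirection"),
        if (rx$rtype == "reversible") "REVERSIBLE" else "LEFT-TO-RIGHT")
  kc <- kegg_id_collection(rx$ids)
  props[[length(props) + 1L]] <-
    res(bp_prop(level, "xref"), add_xref(b, kc$collection, kc$id))
  if (!is.null(rec))
    for (ec in rec$ec_numbers)
      props[[length(props) + 1L]] <- lit(bp_prop(level, "eCNumber"), ec)

  side_props <- function(parts, side) {
    out <- list()
    for (p in parts) {
      ent <- entity_map[[as.character(p$entry_id)]]
      if (is.null(ent))
        stop("export integrity error: reaction ", rx$ids, " participant ",
             p$kegg_id, " has no entity", call. = FALSE)
      out[[length(out) + 1L]] <-
        res(bp_prop(level, side), participant_ref(b, ent, p$stoichiometry,
                                                  sanitize_sid(rx$ids)))
      if (level == 3 && p$stoichiometry != 1) {
        stid <- paste0("st_", sanitize_sid(rx$ids), "_", side, "_",
                       p$entry_id)
        if (!b$has(stid))
          b$add("Stoichiometry", stid,
                list(res("physicalEntity", ent),
                     lit("stoichiometricCoefficient",
                         num_attr(p$stoichiometry), XSD_FLOAT)))
        out[[length(out) + 1L]] <- res("participantStoichiometry", stid)
      }
    }
    out
  }
  props <- c(props, side_props(rx$substrates, "left"),
             side_props(rx$products, "right"))
  b$add(bp_kind(level, "BiochemicalReaction"), rid, props)
  created <- rid

  if (length(rx$modifiers)) {
    cid <- paste0("cat_", sanitize_sid(rx$ids))
    cprops <- list(lit(bp_prop(level, "displayName"),
                       paste0("catalysis of ", rx$ids)),
                   lit(bp_prop(level, "controlType"), "ACTIVATION"),
                   res(bp_prop(level, "controlled"), rid))
    for (m in rx$modifiers) {
      ent <- entity_map[[as.character(m)]]
      if (is.null(ent)) next
      cprops[[length(cprops) + 1L]] <-
        res(bp_prop(level, "controller"),
            participant_ref(b, ent, 1, paste0("cat_", sanitize_sid(rx$ids))))
    }
    b$add(bp_kind(level, "Catalysis"), cid, cprops)
    created <- c(created, cid)
  }
  invisible(created)
}

# deterministic suffix for synthesized modified-state entities
MODIFICATION_SUFFIX <- c("phosphorylation" = "_p", "dephosphorylation" = "_dp",
                         "glycosylation" = "_g", "ubiquitination" = "_u",
                         "methylation" = "_m", "activation" = "_active",
                         "inhibition" = "_inactive", "state change" = "_state")
MODIFICATION_TERM <- c("phosphorylation" = "phosphorylated residue",
                       "dephosphorylation" = "dephosphorylated residue",
                       "glycosylation" = "glycosylated residue",
                       "ubiquitination" = "ubiquitinylated residue",
                       "methylation" = "methylated residue")

# synthesize the target-state variant entity of a base entity
variant_entity <- function(b, base_id, subtype, label) {
  vid <- paste0(base_id, MODIFICATION_SUFFIX[[subtype]])
  if (b$has(vid)) return(vid)
  base <- b$elements[[base_id]]
  props <- list(lit(bp_prop(b$level, "displayName"),
                    paste0(label, " (", sub("^_", "",
                                            MODIFICATION_SUFFIX[[subtype]]),
                           ")")))
  # same entity reference as the base on L3
  for (p in base$props)
    if (p$name == "entityReference")
      props[[length(props) + 1L]] <- p
  if (b$level == 3 && subtype %in% names(MODIFICATION_TERM)) {
    mvid <- paste0("modvoc_", sanitize_sid(subtype))
    if (!b$has(mvid))
      b$add("SequenceModificationVocabulary", mvid,
            list(lit("term", MODIFICATION_TERM[[subtype]])))
    fid <- paste0("mf_", vid)
    b$add("ModificationFeature", fid, list(res("modificationType", mvid)))
    props[[length(props) + 1L]] <- res("feature", fid)
  }
  b$add(base$kind, vid, props)
  vid
}

#' Translate one relation to BioPAX interactions
#'
#' Subtype-dependent: modification-family relations (and
#' activation/inhibition/state change) become a Conversion from the target
#' entity's source state to a synthesized target-state variant, wrapped in
#' a Control whose Controller is the source entity; expression/repression
#' become TemplateReaction + TemplateReactionRegulation on Level 3 (a
#' Conversion + Control fallback on Level 2); binding/association and
#' dissociation become a ComplexAssembly when the product (substrate for a
#' disassembly) is a complex, else a generic Conversion; missing
#' interaction pools both entities in a MolecularInteraction
#' (physicalInteraction on Level 2); indirect effect is a bare Conversion.
#' Every translated relation carries an InteractionVocabulary. Relations
#' pointing to reaction-type entries are wired interaction-to-interaction.
#'
#' @param rel A [kgml_relation()].
#' @param doc Containing [kgml_pathway()].
#' @param store A `resource_store`.
#' @param target A [biopax_target()].
#' @param builder Internal builder; exposed for testing.
#' @param endpoint_map Named map entry id -> element id (entities, or
#'   interactions for reaction-type entries).
#' @return Character vector of created interaction ids (may be empty for
#'   relations with no mappable subtype).
#' @export
relation_to_biopax <- function(rel, doc, store, target, builder = NULL,
                               endpoint_map = NULL) {
  b <- if (is.null(builder)) new_bpx_builder(target$level) else builder
  level <- b$level
  voc <- relation_vocab(rel)
  if (is.null(voc)) return(invisible(character()))
  subtype <- voc$primary_name
  src <- endpoint_map[[as.character(rel$entry1)]]
  tgt <- endpoint_map[[as.character(rel$entry2)]]
  if (is.null(src) || is.null(tgt))
    stop("export integrity error: dangling relation endpoint (",
         rel$entry1, " -> ", rel$entry2, ")", call. = FALSE)
  iv <- add_interaction_vocab(b, subtype)
  base <- paste0("rel_", sanitize_sid(subtype), "_", rel$entry1, "_",
                 rel$entry2)
  ivp <- res(bp_prop(level, "interactionType"), iv)
  tgt_entry <- get_entry(doc, rel$entry2)
  src_entry <- get_entry(doc, rel$entry1)
  tgt_is_interaction <- !is.null(tgt_entry) && tgt_entry$etype == "reaction"
  label <- function(e, fallback) {
    if (is.null(e)) return(fallback)
    if (!is.null(e$graphics) && !is.na(e$graphics$label)) e$graphics$label
    else if (length(e$names)) e$names[1] else fallback
  }
  created <- character()

  make_control <- function(controlled_id, control_type) {
    cid <- paste0("ctrl_", base)
    b$add(bp_kind(level, "Control"), cid,
          list(lit(bp_prop(level, "displayName"),
                   paste0(voc$primary$label, " control")),
               lit(bp_prop(level, "controlType"), control_type),
               res(bp_prop(level, "controller"),
                   participant_ref(b, src, 1, paste0("c_", base))),
               res(bp_prop(level, "controlled"), controlled_id), ivp))
    cid
  }

  if (subtype %in% c(names(MODIFICATION_SUFFIX))) {
    # conversion of the target from source state to target state,
    # controlled by the source entity
    conv_id <- paste0("conv_", base)
    if (tgt_is_interaction) {
      # relation targets a reaction: control that interaction directly
      created <- c(created,
                   make_control(tgt, if (subtype == "inhibition")
                     "INHIBITION" else "ACTIVATION"))
      return(invisible(created))
    }
    tlab <- label(tgt_entry, tgt)
    from <- tgt
    to <- variant_entity(b, tgt, subtype, tlab)
    if (subtype == "dephosphorylation") { tmp <- from; from <- to; to <- tmp }
    b$add(bp_kind(level, "Conversion"), conv_id,
          list(lit(bp_prop(level, "displayName"),
                   paste0(voc$primary$label, " of ", tlab)),
               res(bp_prop(level, "left"),
                   participant_ref(b, from, 1, paste0("l_", base))),
               res(bp_prop(level, "right"),
                   participant_ref(b, to, 1, paste0("r_", base))), ivp))
    created <- c(created, conv_id,
                 make_control(conv_id, if (subtype == "inhibition")
                   "INHIBITION" else "ACTIVATION"))
  } else if (subtype %in% c("expression", "repression")) {
    if (level == 3) {
      tr_id <- paste0("templ_", base)
      b$add("TemplateReaction", tr_id,
            list(lit("displayName",
                     paste0("expression of ", label(tgt_entry, tgt))),
                 res("product", tgt), ivp))
      reg_id <- paste0("templreg_", base)
      b$add("TemplateReactionRegulation", reg_id,
            list(lit("displayName", paste0(subtype, " regulation")),
                 lit("controlType", if (subtype == "repression")
                   "INHIBITION" else "ACTIVATION"),
                 res("controller", src),
                 res("controlled", tr_id), ivp))
      created <- c(created, tr_id, reg_id)
    } else {
      conv_id <- paste0("conv_", base)
      b$add(bp_kind(2, "Conversion"), conv_id,
            list(lit(bp_prop(2, "displayName"),
                     paste0("expression of ", label(tgt_entry, tgt))),
                 res(bp_prop(2, "right"),
                     participant_ref(b, tgt, 1, paste0("r_", base))), ivp))
      created <- c(created, conv_id,
                   make_control(conv_id, if (subtype == "repression")
                     "INHIBITION" else "ACTIVATION"))
    }
  } else if (subtype %in% c("binding/association", "dissociation")) {
    assembling <- subtype == "binding/association"
    complex_end_entry <- if (assembling) tgt_entry else src_entry
    is_complex <- !is.null(complex_end_entry) &&
      complex_end_entry$etype == "group"
    kind <- if (is_complex) "ComplexAssembly" else "Conversion"
    conv_id <- paste0(if (is_complex) "ca_" else "conv_", base)
    left <- if (assembling) src else src
    right <- tgt
    b$add(bp_kind(level, kind), conv_id,
          list(lit(bp_prop(level, "displayName"), voc$primary$label),
               res(bp_prop(level, "left"),
                   participant_ref(b, left, 1, paste0("l_", base))),
               res(bp_prop(level, "right"),
                   participant_ref(b, right, 1, paste0("r_", base))), ivp))
    created <- c(created, conv_id)
  } else if (subtype == "missing interaction") {
    mi_id <- paste0("mi_", base)
    b$add(bp_kind(level, "MolecularInteraction"), mi_id,
          list(lit(bp_prop(level, "displayName"), "missing interaction"),
               res(bp_prop(level, "participant"),
                   participant_ref(b, src, 1, paste0("p1_", base))),
               res(bp_prop(level, "participant"),
                   participant_ref(b, tgt, 1, paste0("p2_", base))), ivp))
    created <- c(created, mi_id)
  } else {   # indirect effect
    conv_id <- paste0("conv_", base)
    b$add(bp_kind(level, "Conversion"), conv_id,
          list(lit(bp_prop(level, "displayName"), "indirect effect"),
               res(bp_prop(level, "left"),
                   participant_ref(b, src, 1, paste0("l_", base))),
               res(bp_prop(level, "right"),
                   participant_ref(b, tgt, 1, paste0("r_", base))), ivp))
    created <- c(created, conv_id)
  }
  invisible(created)
}

# ---- document assembly ------------------------------------------------------

#' Translate a preprocessed pathway document to BioPAX
#'
#' Builds the pathway object that owns all interactions, one physical
#' entity per surviving entry, one BiochemicalReaction (+ Catalysis when
#' enzymes are annotated) per reaction, and the subtype-dependent
#' interactions for every relation, then serializes to OWL/RDF-XML.
#' Structural self-validation (every `rdf:resource` resolves to an
#' `rdf:ID` in the document) runs before returning.
#'
#' @param doc A preprocessed [kgml_pathway()].
#' @param store A `resource_store`.
#' @param target A [biopax_target()].
#' @return An `xml2` document; the intermediate element list is in
#'   `attr(, "elements")` and the entry-to-element log in
#'   `attr(, "element_log")`.
#' @export
translate_biopax <- function(doc, store, target = biopax_target(3)) {
  b <- new_bpx_builder(target$level)
  entity_map <- list()   # entry id -> element id (entities)
  log <- list()
  for (e in doc$entries) {
    if (e$etype == "reaction") next
    eid <- entry_to_element(e, store, target, b, doc)
    entity_map[[as.character(e$id)]] <- eid
    log[[length(log) + 1L]] <- list(kgml = paste0("entry:", e$id),
                                    element = eid)
  }
  interaction_ids <- character()
  rx_id_map <- character()   # kegg reaction id -> element id
  for (rx in doc$reactions) {
    ids <- reaction_to_biopax(rx, doc, store, target, b, entity_map)
    interaction_ids <- c(interaction_ids, ids)
    rx_id_map[[rx$ids]] <- ids[1]
    log[[length(log) + 1L]] <- list(kgml = paste0("reaction:", rx$ids),
                                    element = ids[1])
  }
  # endpoint map: entities, plus interactions for reaction-type entries
  endpoint_map <- entity_map
  for (e in doc$entries) {
    if (e$etype != "reaction") next
    hit <- e$names[e$names %in% names(rx_id_map)]
    if (length(hit)) {
      endpoint_map[[as.character(e$id)]] <- rx_id_map[[hit[1]]]
      log[[length(log) + 1L]] <- list(kgml = paste0("entry:", e$id),
                                      element = rx_id_map[[hit[1]]])
    }
  }
  for (i in seq_along(doc$relations)) {
    ids <- relation_to_biopax(doc$relations[[i]], doc, store, target, b,
                              endpoint_map)
    interaction_ids <- c(interaction_ids, ids)
    if (length(ids))
      log[[length(log) + 1L]] <- list(kgml = paste0("relation:", i),
                                      element = ids[1])
  }

  # pathway object owning every interaction
  pw_id <- paste0("pw_", sanitize_sid(doc$name))
  pprops <- list(lit(bp_prop(target$level, "displayName"),
                     if (nzchar(doc$title)) doc$title else doc$name))
  kc <- kegg_id_collection(doc$name)
  pprops[[length(pprops) + 1L]] <-
    res(bp_prop(target$level, "xref"), add_xref(b, kc$collection, kc$id))
  if (nzchar(doc$org)) {
    bs_id <- "biosource_org"
    b$add(bp_kind(target$level, "BioSource"), bs_id,
          list(lit(bp_prop(target$level, "name"), doc$org)))
    pprops[[length(pprops) + 1L]] <- res(bp_prop(target$level, "organism"),
                                         bs_id)
  }
  for (iid in interaction_ids)
    pprops[[length(pprops) + 1L]] <-
      res(bp_prop(target$level, "pathwayComponent"), iid)
  b$add(bp_kind(target$level, "Pathway"), pw_id, pprops)

  x <- serialize_biopax(b)
  v <- validate_biopax_structure(x)
  if (nrow(v))
    stop("BioPAX structural self-validation failed:\n",
         paste(v$message, collapse = "\n"), call. = FALSE)
  attr(x, "elements") <- b$elements
  attr(x, "element_log") <- log
  x
}

serialize_biopax <- function(b) {
  ns <- if (b$level == 3) BP3_NS else BP2_NS
  x <- xml2::xml_new_root("rdf:RDF", "xmlns:rdf" = RDF_NS,
                          "xmlns:bp" = ns, "xmlns:owl" = OWL_NS,
                          "xml:base" = "http://kgmlconv.local/model#")
  onto <- xml2::xml_add_child(x, "owl:Ontology", "rdf:about" = "")
  xml2::xml_add_child(onto, "owl:imports", "rdf:resource" = ns)
  for (el in b$elements[order(names(b$elements))]) {
    node <- xml2::xml_add_child(x, paste0("bp:", el$kind),
                                "rdf:ID" = el$id)
    for (p in el$props) {
      if (p$type == "literal") {
        pn <- xml2::xml_add_child(node, paste0("bp:", p$name),
                                  "rdf:datatype" = p$datatype)
        xml2::xml_text(pn) <- p$value
      } else {
        xml2::xml_add_child(node, paste0("bp:", p$name),
                            "rdf:resource" = paste0("#", p$value))
      }
    }
  }
  x
}

#' Structural self-validation of a generated BioPAX document
#'
#' Every `rdf:resource` fragment reference must resolve to an `rdf:ID` in
#' the same document; Catalysis/Control elements must carry both a
#' controller and a controlled process.
#'
#' @param x An `xml2` BioPAX document.
#' @return A tibble of findings (empty when sound).
#' @export
validate_biopax_structure <- function(x) {
  msgs <- character()
  nodes <- xml2::xml_find_all(x, "//*[@rdf:ID]")
  ids <- xml2::xml_attr(nodes, "rdf:ID")
  refs <- xml2::xml_attr(xml2::xml_find_all(x, "//*[@rdf:resource]"),
                         "rdf:resource")
  refs <- refs[!is.na(refs) & startsWith(refs, "#")]
  for (r in unique(substring(refs, 2)))
    if (!r %in% ids)
      msgs <- c(msgs, paste("unresolvable rdf:resource reference:", r))
  for (n in nodes[grepl("Catalysis|Control|catalysis|control",
                        xml2::xml_name(nodes))]) {
    kids <- xml2::xml_name(xml2::xml_children(n))
    has_controller <- any(kids %in% c("controller", "CONTROLLER"))
    has_controlled <- any(kids %in% c("controlled", "CONTROLLED"))
    if (!has_controller || !has_controlled)
      msgs <- c(msgs, paste("incomplete control element:",
                            xml2::xml_attr(n, "rdf:ID")))
  }
  if (length(msgs) == 0L)
    return(tibble::tibble(message = character()))
  tibble::tibble(message = msgs)
}

#' Write a BioPAX document to a file
#'
#' @param x An `xml2` document from [translate_biopax()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_biopax <- function(x, path) {
  xml2::write_xml(x, path)
  invisible(path)
}
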