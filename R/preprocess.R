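# Correction pipeline applied to parsed KGML before any conversion:
# prune entries that have no physical counterpart, disassemble bundled
# reactions, complete reactions against their store equations, canonicalize
# glycan/drug identifiers, merge graphical duplicates and drop
# compound-relations that shadow reactions.

#' Preprocessing options
#'
#' All flags are independent. Orphan removal defaults off: entries outside
#' every relation and reaction are harmless for most uses and their removal
#' is a modeling preference, not a correction.
#'
#' @param remove_pathway_refs Drop entries of type `map` (links to other
#'   pathway maps; not physical instances).
#' @param remove_orphans Drop entries referenced by no relation, no reaction
#'   participant or modifier list, and no group component.
#' @param remove_white_nodes Drop gene/ortholog/enzyme entries whose
#'   graphics background is white — KEGG's marker for gene products not
#'   confirmed in the organism. Compounds are never removed by color.
#' @param complete_reactions Complete every reaction against its store
#'   equation (participants, stoichiometry, reversibility, enzymes).
#' @param unbundle Split reaction objects carrying several KEGG reaction
#'   identifiers into one object per identifier.
#' @param merge_duplicates Collapse graphical copies of the same entry.
#' @param drop_compound_relations Remove relations whose only subtype is
#'   `compound` when the document also carries reactions (they duplicate the
#'   reaction information).
#' @param canonicalize_glycans Rewrite glycan/drug identifiers to their KEGG
#'   COMPOUND synonym wherever one exists.
#' @return A list of class `preprocess_options`.
#' @export
preprocess_options <- function(remove_pathway_refs = TRUE,
                               remove_orphans = FALSE,
                               remove_white_nodes = TRUE,
                               complete_reactions = TRUE,
                               unbundle = TRUE,
                               merge_duplicates = TRUE,
                               drop_compound_relations = TRUE,
                               canonicalize_glycans = TRUE) {
  structure(list(remove_pathway_refs = remove_pathway_refs,
                 remove_orphans = remove_orphans,
                 remove_white_nodes = remove_white_nodes,
                 complete_reactions = complete_reactions,
                 unbundle = unbundle,
                 merge_duplicates = merge_duplicates,
                 drop_compound_relations = drop_compound_relations,
                 canonicalize_glycans = canonicalize_glycans),
            class = "preprocess_options")
}

empty_log <- function() {
  tibble::tibble(step = character(), action = character(),
                 element = character(), detail = character())
}

log_row <- function(step, action, element, detail) {
  tibble::tibble(step = step, action = action, element = as.character(element),
                 detail = detail)
}

# drop the given entry ids and trim relations/reactions/groups consistently
drop_entries <- function(doc, ids, step, log) {
  if (length(ids) == 0L) return(list(doc = doc, log = log))
  keep <- vapply(doc$entries, function(e) !(e$id %in% ids), logical(1))
  for (e in doc$entries[!keep])
    log <- rbind(log, log_row(step, "remove-entry", e$id,
                              paste0(e$etype, " ",
                                     paste(e$names, collapse = " "))))
  doc$entries <- doc$entries[keep]
  rel_keep <- vapply(doc$relations, function(r)
    !(r$entry1 %in% ids || r$entry2 %in% ids), logical(1))
  for (i in which(!rel_keep))
    log <- rbind(log, log_row(step, "remove-relation", i,
                              paste(doc$relations[[i]]$entry1, "->",
                                    doc$relations[[i]]$entry2)))
  doc$relations <- doc$relations[rel_keep]
  doc$entries <- lapply(doc$entries, function(e) {
    if (length(e$components)) e$components <- setdiff(e$components, ids)
    e
  })
  doc$reactions <- lapply(doc$reactions, function(rx) {
    rx$substrates <- Filter(function(p) !(p$entry_id %in% ids), rx$substrates)
    rx$products <- Filter(function(p) !(p$entry_id %in% ids), rx$products)
    rx$modifiers <- setdiff(rx$modifiers, ids)
    rx
  })
  list(doc = doc, log = log)
}

orphan_ids <- function(doc) {
  used <- integer()
  for (r in doc$relations) used <- c(used, r$entry1, r$entry2)
  for (rx in doc$reactions) {
    used <- c(used, rx$modifiers,
              vapply(rx$substrates, function(p) p$entry_id, integer(1)),
              vapply(rx$products, function(p) p$entry_id, integer(1)))
  }
  for (e in doc$entries) used <- c(used, e$components)
  # a group with components is connected to the pathway through its members
  for (e in doc$entries)
    if (e$etype == "group" && length(e$components)) used <- c(used, e$id)
  ids <- vapply(doc$entries, function(e) e$id, integer(1))
  setdiff(ids, used)
}

is_white_node <- function(e) {
  !is.null(e$graphics) && !is.na(e$graphics$bgcolor) &&
    toupper(e$graphics$bgcolor) == "#FFFFFF" &&
    e$etype %in% c("gene", "ortholog", "enzyme")
}

#' Prune map references, white nodes and orphans
#'
#' Removal order is pathway references, then white nodes, then orphans —
#' orphan status is re-evaluated after the first two removals so entries
#' stranded by them are caught. All relations and reactions touching a
#' removed entry are removed or trimmed consistently.
#'
#' @param doc A [kgml_pathway()].
#' @param opts A [preprocess_options()].
#' @return The pruned document, with the removal log in
#'   `attr(, "prune_log")`.
#' @export
prune_entries <- function(doc, opts = preprocess_options()) {
  log <- empty_log()
  if (isTRUE(opts$remove_pathway_refs)) {
    ids <- vapply(Filter(function(e) e$etype == "map", doc$entries),
                  function(e) e$id, integer(1))
    res <- drop_entries(doc, ids, "prune-pathway-refs", log)
    doc <- res$doc; log <- res$log
  }
  if (isTRUE(opts$remove_white_nodes)) {
    ids <- vapply(Filter(is_white_node, doc$entries),
                  function(e) e$id, integer(1))
    res <- drop_entries(doc, ids, "prune-white-nodes", log)
    doc <- res$doc; log <- res$log
  }
  if (isTRUE(opts$remove_orphans)) {
    res <- drop_entries(doc, orphan_ids(doc), "prune-orphans", log)
    doc <- res$doc; log <- res$log
  }
  attr(doc, "prune_log") <- log
  doc
}

#' Disassemble bundled reaction objects
#'
#' A single KGML reaction object may carry several KEGG REACTION
#' identifiers; each becomes its own reaction object (initially with copies
#' of the original participant lists, to be corrected by
#' [complete_reaction()]). The multiset of reaction identifiers over the
#' document is conserved.
#'
#' @param doc A [kgml_pathway()].
#' @return The document with every reaction carrying exactly one identifier.
#' @export
unbundle_reactions <- function(doc) {
  out <- list()
  for (rx in doc$reactions) {
    if (length(rx$ids) == 1L) {
      out[[length(out) + 1L]] <- rx
    } else {
      for (id in rx$ids) {
        r1 <- rx
        r1$ids <- id
        out[[length(out) + 1L]] <- r1
      }
    }
  }
  doc$reactions <- out
  rewire_modifiers(doc)
}

# does any (alias-closed) identifier of entry `e` match `id`?
entry_matches_id <- function(e, id, store) {
  cid <- canonical_compound_id(store, id)
  any(vapply(e$names, function(n)
    canonical_compound_id(store, n) == cid, logical(1)))
}

#' Complete one reaction against its store equation
#'
#' Sets the reversibility from the store record, matches every equation
#' participant to the existing participant references through alias-aware
#' identifier comparison, appends unmatched equation participants (creating
#' new compound entries in the document where none exists), copies
#' stoichiometry from the parsed equation (symbolic coefficients evaluated
#' at n = 1 and kept verbatim), and wires catalyzing enzymes: every document
#' entry whose gene record carries one of the record's EC numbers joins the
#' modifier set. Existing participants absent from the equation are never
#' deleted, only logged as surplus.
#'
#' @param doc The containing [kgml_pathway()] (new entries may be added).
#' @param rx A [kgml_reaction()] with exactly one identifier.
#' @param store A `resource_store`.
#' @return A list with `doc` (possibly extended), `reaction` (the completed
#'   reaction) and `log` (a tibble of every addition/decision).
#' @export
complete_reaction <- function(doc, rx, store) {
  log <- empty_log()
  if (length(rx$ids) != 1L)
    stop("complete_reaction requires an unbundled reaction", call. = FALSE)
  rec <- store$reactions[[rx$ids]]
  if (is.null(rec)) {
    log <- rbind(log, log_row("complete", "error", rx$ids,
                              "reaction id absent from store; left untouched"))
    return(list(doc = doc, reaction = rx, log = log))
  }
  new_rtype <- if (rec$reversible) "reversible" else "irreversible"
  if (!identical(rx$rtype, new_rtype)) {
    log <- rbind(log, log_row("complete", "set-reversibility", rx$ids,
                              new_rtype))
    rx$rtype <- new_rtype
  }
  eq <- parse_equation(rec$equation)

  next_entry_id <- function() max(0L, vapply(doc$entries, function(e) e$id,
                                             integer(1))) + 1L

  match_side <- function(refs, eq_parts, side) {
    matched_ref <- rep(FALSE, length(refs))
    for (p in eq_parts) {
      hit <- NA_integer_
      for (k in seq_along(refs)) {
        if (matched_ref[k]) next
        if (canonical_compound_id(store, refs[[k]]$kegg_id) ==
            canonical_compound_id(store, p$id)) { hit <- k; break }
      }
      if (!is.na(hit)) {
        matched_ref[hit] <- TRUE
        if (refs[[hit]]$stoichiometry != p$coeff ||
            !identical(refs[[hit]]$symbolic_coeff, p$symbolic)) {
          refs[[hit]]$stoichiometry <- p$coeff
          refs[[hit]]$symbolic_coeff <- p$symbolic
          log <<- rbind(log, log_row("complete", "set-stoichiometry",
                                     rx$ids,
                                     paste0(side, " ", p$id, " x",
                                            num_attr(p$coeff))))
        }
        next
      }
      # no participant ref: find (or create) an entry for this species.
      # Prefer an entry already wired to this reaction, else the lowest id.
      cand <- Filter(function(e) e$etype %in% c("compound", "other") &&
                       entry_matches_id(e, p$id, store), doc$entries)
      ent <- NULL
      if (length(cand)) {
        wired <- unique(c(
          vapply(rx$substrates, function(q) q$entry_id, integer(1)),
          vapply(rx$products, function(q) q$entry_id, integer(1))))
        in_rx <- Filter(function(e) e$id %in% wired, cand)
        pool <- if (length(in_rx)) in_rx else cand
        ids <- vapply(pool, function(e) e$id, integer(1))
        ent <- pool[[which.min(ids)]]
        if (length(cand) > 1L)
          log <<- rbind(log, log_row("complete", "tie-break", rx$ids,
                                     paste0(p$id, " -> entry ", ent$id)))
      } else {
        ent <- kgml_entry(id = next_entry_id(), names = p$id,
                          etype = "compound")
        doc$entries[[length(doc$entries) + 1L]] <<- ent
        log <<- rbind(log, log_row("complete", "add-entry", ent$id, p$id))
      }
      refs[[length(refs) + 1L]] <- kgml_participant(
        entry_id = ent$id, kegg_id = p$id, stoichiometry = p$coeff,
        symbolic_coeff = p$symbolic)
      log <<- rbind(log, log_row("complete", "add-participant", rx$ids,
                                 paste0(side, " ", p$id, " x",
                                        num_attr(p$coeff))))
    }
    for (k in which(!matched_ref))
      log <<- rbind(log, log_row("complete", "surplus-participant", rx$ids,
                                 paste0(side, " ", refs[[k]]$kegg_id,
                                        " (kept, absent from equation)")))
    refs
  }
  rx$substrates <- match_side(rx$substrates, eq$substrates, "substrate")
  rx$products <- match_side(rx$products, eq$products, "product")

  # enzymes via EC numbers
  if (length(rec$ec_numbers)) {
    matched_ec <- character()
    for (i in seq_along(doc$entries)) {
      e <- doc$entries[[i]]
      if (!e$etype %in% c("gene", "enzyme", "ortholog")) next
      ecs <- unique(unlist(lapply(e$names, function(n) {
        g <- store_lookup(store, "gene", n)
        if (is.null(g)) character() else g$ec_numbers
      })))
      common <- intersect(ecs, rec$ec_numbers)
      if (length(common)) {
        matched_ec <- c(matched_ec, common)
        if (!e$id %in% rx$modifiers) {
          rx$modifiers <- sort(c(rx$modifiers, e$id))
          log <- rbind(log, log_row("complete", "add-modifier", rx$ids,
                                    paste0("entry ", e$id, " (EC ",
                                           paste(common, collapse = " "), ")")))
        }
        if (!rx$ids %in% e$reaction_attr) {
          doc$entries[[i]]$reaction_attr <- c(e$reaction_attr, rx$ids)
        }
      }
    }
    for (ec in setdiff(rec$ec_numbers, matched_ec))
      log <- rbind(log, log_row("complete", "unmatched-ec", rx$ids, ec))
  }
  list(doc = doc, reaction = rx, log = log)
}

#' Complete every reaction of a document
#'
#' @param doc A [kgml_pathway()] (reactions should be unbundled first).
#' @param store A `resource_store`.
#' @return A list with `doc` and `log`.
#' @export
complete_reactions <- function(doc, store) {
  log <- empty_log()
  for (i in seq_along(doc$reactions)) {
    res <- complete_reaction(doc, doc$reactions[[i]], store)
    doc <- res$doc
    doc$reactions[[i]] <- res$reaction
    log <- rbind(log, res$log)
  }
  list(doc = doc, log = log)
}

#' Rewrite glycan/drug identifiers to canonical compound identifiers
#'
#' Reaction equations and compound attributes (formula, weight) live on the
#' KEGG COMPOUND identifier; working with the compound synonym avoids
#' phantom mismatches and duplicated species. Entries that become
#' identifier-identical after this pass are merged later by
#' [merge_duplicate_entries()], not here.
#'
#' @param doc A [kgml_pathway()].
#' @param store A `resource_store`.
#' @return The canonicalized document.
#' @export
canonicalize_glycans <- function(doc, store) {
  can <- function(x) vapply(x, function(id)
    canonical_compound_id(store, id), "")
  doc$entries <- lapply(doc$entries, function(e) {
    if (length(e$names)) e$names <- unname(can(e$names))
    e
  })
  doc$reactions <- lapply(doc$reactions, function(rx) {
    fix <- function(ps) lapply(ps, function(p) {
      p$kegg_id <- canonical_compound_id(store, p$kegg_id)
      p
    })
    rx$substrates <- fix(rx$substrates)
    rx$products <- fix(rx$products)
    rx
  })
  doc
}

#' Merge graphical duplicates of the same entry
#'
#' Entries with identical type and identical sorted identifier lists are
#' graphical copies; a model needs one element for all of them. The lowest
#' id becomes the representative; relations, reaction participants, group
#' components and modifier sets are rewritten through the merge map (so an
#' entry drawn twice, each copy catalyzing a different reaction, ends up
#' catalyzing both), and relations made identical by the rewrite are
#' deduplicated. Graphics are dropped from merged representatives.
#'
#' @param doc A [kgml_pathway()] (glycan canonicalization should run first).
#' @return A list with `doc` and `merge_map`
#'   (`list(representative = named integer, groups = list of merged id sets)`).
#' @export
merge_duplicate_entries <- function(doc) {
  ids <- vapply(doc$entries, function(e) e$id, integer(1))
  keys <- vapply(doc$entries, function(e)
    if (length(e$names) == 0L) paste0("#anon#", e$id)
    else paste(e$etype, paste(sort(e$names), collapse = " ")), "")
  rep_map <- stats::setNames(ids, as.character(ids))
  groups <- list()
  for (key in unique(keys[duplicated(keys)])) {
    members <- ids[keys == key]
    repr <- min(members)
    rep_map[as.character(members)] <- repr
    groups[[length(groups) + 1L]] <- sort(members)
  }
  remap <- function(x) unname(rep_map[as.character(x)])
  if (length(groups)) {
    reprs <- vapply(groups, min, integer(1))
    merged_away <- setdiff(unlist(groups), reprs)
    # union of the copies' reaction attributes, keyed by representative id
    rattr <- lapply(groups, function(g)
      sort(unique(unlist(lapply(doc$entries[ids %in% g],
                                function(e) e$reaction_attr)))))
    names(rattr) <- as.character(reprs)
    keep <- !(ids %in% merged_away)
    doc$entries <- lapply(doc$entries[keep], function(e) {
      if (e$id %in% reprs) {
        e$graphics <- NULL
        e$reaction_attr <- rattr[[as.character(e$id)]]
      }
      if (length(e$components))
        e$components <- sort(unique(remap(e$components)))
      e
    })
    doc$relations <- lapply(doc$relations, function(r) {
      r$entry1 <- remap(r$entry1)
      r$entry2 <- remap(r$entry2)
      r
    })
    # dedupe identical relations
    sig <- vapply(doc$relations, function(r)
      paste(r$entry1, r$entry2, r$rtype,
            paste(vapply(r$subtypes, function(s)
              paste0(s$name, "=", s$value), ""), collapse = ";")), "")
    doc$relations <- doc$relations[!duplicated(sig)]
    doc$reactions <- lapply(doc$reactions, function(rx) {
      fix <- function(ps) lapply(ps, function(p) {
        if (!is.na(p$entry_id)) p$entry_id <- remap(p$entry_id)
        p
      })
      rx$substrates <- fix(rx$substrates)
      rx$products <- fix(rx$products)
      rx$modifiers <- sort(unique(remap(rx$modifiers)))
      rx
    })
  }
  list(doc = doc,
       merge_map = list(representative = rep_map, groups = groups))
}

#' Drop relations of subtype 'compound' that shadow reactions
#'
#' KEGG draws a compound shared by two successive reactions as a relation of
#' subtype `compound`; translating both the reactions and these relations
#' would duplicate the information. When the document carries at least one
#' reaction, every relation whose subtypes consist solely of `compound` is
#' removed; relations carrying any other subtype are kept.
#'
#' @param doc A [kgml_pathway()].
#' @return The deduplicated document.
#' @export
dedupe_compound_relations <- function(doc) {
  if (length(doc$reactions) == 0L) return(doc)
  keep <- vapply(doc$relations, function(r) {
    nms <- vapply(r$subtypes, function(s) s$name, "")
    !(length(nms) > 0L && all(nms %in% c("compound", "hidden compound")))
  }, logical(1))
  doc$relations <- doc$relations[keep]
  doc
}

#' Run the full preprocessing pipeline
#'
#' Order: glycan canonicalization, pruning (pathway refs, white nodes,
#' orphans), unbundling, reaction completion, compound-relation removal,
#' duplicate merging (merging runs last so earlier steps see the original
#' copies).
#'
#' @param doc A [kgml_pathway()].
#' @param store A `resource_store`.
#' @param opts A [preprocess_options()].
#' @return A list with `doc`, `log` (tibble of all actions) and `merge_map`.
#' @export
preprocess_pathway <- function(doc, store, opts = preprocess_options()) {
  log <- empty_log()
  if (isTRUE(opts$canonicalize_glycans))
    doc <- canonicalize_glycans(doc, store)
  doc <- prune_entries(doc, opts)
  log <- rbind(log, attr(doc, "prune_log"))
  attr(doc, "prune_log") <- NULL
  if (isTRUE(opts$unbundle))
    doc <- unbundle_reactions(doc)
  if (isTRUE(opts$complete_reactions)) {
    res <- complete_reactions(doc, store)
    doc <- res$doc
    log <- rbind(log, res$log)
  }
  if (isTRUE(opts$drop_compound_relations))
    doc <- dedupe_compound_relations(doc)
  merge_map <- list(representative = stats::setNames(
    vapply(doc$entries, function(e) e$id, integer(1)),
    as.character(vapply(doc$entries, function(e) e$id, integer(1)))),
    groups = list())
  if (isTRUE(opts$merge_duplicates)) {
    res <- merge_duplicate_entries(doc)
    doc <- res$doc
    merge_map <- res$merge_map
    for (g in merge_map$groups)
      log <- rbind(log, log_row("merge", "merge-entries", min(g),
                                paste(g, collapse = " ")))
  }
  list(doc = doc, log = log, merge_map = merge_map)
}
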