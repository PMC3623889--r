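# KGML document model and lossless XML I/O.
#
# A pathway document is held as a plain S3 list ("kgml_pathway") whose
# entries, relations and reactions mirror the KGML vocabulary one-to-one.
# Unknown XML attributes are kept in an `extra` side map so that
# parse -> write -> parse is the identity on everything we model.

KGML_ENTRY_TYPES <- c("ortholog", "enzyme", "gene", "group", "compound",
                      "map", "reaction", "other")
KGML_RELATION_TYPES <- c("ECrel", "PPrel", "GErel", "PCrel", "maplink")
KGML_SUBTYPE_NAMES <- c("activation", "inhibition", "expression", "repression",
                        "indirect effect", "state change", "binding/association",
                        "dissociation", "missing interaction", "phosphorylation",
                        "dephosphorylation", "glycosylation", "ubiquitination",
                        "methylation", "compound", "hidden compound")

#' Construct a KGML entry
#'
#' Entries are the nodes of a KGML pathway map: genes, orthologs, enzymes,
#' compounds, referenced maps, groups (complexes) and, occasionally,
#' reactions. Identifiers in `names` keep their KEGG namespace prefix
#' (`hsa:`, `cpd:`, `gl:`, `path:`, ...).
#'
#' @param id Document-local positive integer identifier.
#' @param names Character vector of KEGG identifiers (split on whitespace in
#'   the XML `name` attribute).
#' @param etype Entry type, one of `r paste(KGML_ENTRY_TYPES, collapse = ", ")`.
#' @param reaction_attr KEGG reaction identifiers this entry catalyzes
#'   (the XML `reaction` attribute, split on whitespace).
#' @param graphics Optional list from [kgml_graphics()].
#' @param components Integer vector of member entry ids (groups only).
#' @param extra Named character vector of unmodeled XML attributes.
#' @return A list of class `kgml_entry`.
#' @export
kgml_entry <- function(id, names, etype, reaction_attr = character(),
                       graphics = NULL, components = integer(),
                       extra = character()) {
  stopifnot(length(id) == 1L, is.finite(id), id > 0)
  etype <- match.arg(etype, KGML_ENTRY_TYPES)
  if (etype == "group" && length(components) == 0L)
    warning("group entry ", id, " has no components", call. = FALSE)
  structure(list(id = as.integer(id), names = as.character(names),
                 etype = etype, reaction_attr = as.character(reaction_attr),
                 graphics = graphics, components = as.integer(components),
                 extra = extra),
            class = "kgml_entry")
}

#' Construct a graphics record for an entry
#'
#' @param label Display label.
#' @param bgcolor,fgcolor Hex colors (`#RRGGBB`) or `NA`.
#' @param x,y,width,height Layout numbers or `NA`.
#' @param shape Shape keyword (rectangle, circle, roundrectangle, line).
#' @param extra Named character vector of unmodeled attributes.
#' @return A list of class `kgml_graphics`.
#' @export
kgml_graphics <- function(label = NA_character_, bgcolor = NA_character_,
                          fgcolor = NA_character_, x = NA_real_, y = NA_real_,
                          width = NA_real_, height = NA_real_,
                          shape = NA_character_, extra = character()) {
  for (col in c(bgcolor, fgcolor))
    if (!is.na(col) && !grepl("^#[0-9A-Fa-f]{6}$", col))
      stop("invalid color '", col, "' (expected #RRGGBB)", call. = FALSE)
  structure(list(label = label, bgcolor = bgcolor, fgcolor = fgcolor,
                 x = as.numeric(x), y = as.numeric(y),
                 width = as.numeric(width), height = as.numeric(height),
                 shape = shape, extra = extra),
            class = "kgml_graphics")
}

#' Construct a KGML relation
#'
#' Relations are the edges of signaling maps ("A activates B"). Subtypes are
#' (name, value) pairs from the KGML closed vocabulary; the value carries
#' KEGG's arrow glyph or, for subtype `compound`, an entry id.
#'
#' @param entry1,entry2 Source/target entry ids.
#' @param rtype Relation type, one of
#'   `r paste(KGML_RELATION_TYPES, collapse = ", ")`.
#' @param subtypes List of `list(name =, value =)` pairs.
#' @param extra Named character vector of unmodeled attributes.
#' @return A list of class `kgml_relation`.
#' @export
kgml_relation <- function(entry1, entry2, rtype, subtypes = list(),
                          extra = character()) {
  rtype <- match.arg(rtype, KGML_RELATION_TYPES)
  for (st in subtypes) {
    if (!st$name %in% KGML_SUBTYPE_NAMES)
      stop("unknown relation subtype '", st$name, "'", call. = FALSE)
  }
  structure(list(entry1 = as.integer(entry1), entry2 = as.integer(entry2),
                 rtype = rtype, subtypes = subtypes, extra = extra),
            class = "kgml_relation")
}

#' Construct a reaction participant reference
#'
#' @param entry_id Entry id of the participant (NA when the participant was
#'   added from the store equation and no entry existed yet).
#' @param kegg_id KEGG identifier of the species.
#' @param stoichiometry Positive coefficient; for symbolic coefficients this
#'   is the value at n = 1.
#' @param symbolic_coeff Verbatim symbolic coefficient (e.g. `"n"`, `"n+1"`)
#'   or `NA`.
#' @return A list of class `kgml_participant`.
#' @export
kgml_participant <- function(entry_id, kegg_id, stoichiometry = 1,
                             symbolic_coeff = NA_character_) {
  stopifnot(stoichiometry > 0)
  structure(list(entry_id = as.integer(entry_id), kegg_id = kegg_id,
                 stoichiometry = as.numeric(stoichiometry),
                 symbolic_coeff = symbolic_coeff),
            class = "kgml_participant")
}

#' Construct a KGML reaction object
#'
#' One XML reaction object may be "bundled", i.e. carry several KEGG
#' REACTION identifiers; `ids` preserves them in document order.
#' Modifiers (catalyzing enzymes) are entry ids derived from entries whose
#' `reaction` attribute names one of this reaction's ids; they are never
#' serialized, only re-derived on parse.
#'
#' @param ids Character vector of KEGG reaction identifiers.
#' @param rtype `"reversible"` or `"irreversible"`.
#' @param substrates,products Lists of [kgml_participant()].
#' @param modifiers Integer vector of catalyzing entry ids.
#' @param extra Named character vector of unmodeled attributes.
#' @return A list of class `kgml_reaction`.
#' @export
kgml_reaction <- function(ids, rtype, substrates = list(), products = list(),
                          modifiers = integer(), extra = character()) {
  stopifnot(length(ids) >= 1L)
  rtype <- match.arg(rtype, c("reversible", "irreversible"))
  structure(list(ids = as.character(ids), rtype = rtype,
                 substrates = substrates, products = products,
                 modifiers = as.integer(modifiers), extra = extra),
            class = "kgml_reaction")
}

#' Construct a KGML pathway document
#'
#' @param name KEGG pathway identifier (e.g. `"path:hsa04010"`).
#' @param org Organism code.
#' @param number Map number.
#' @param title Free-text title.
#' @param entries,relations,reactions Ordered lists of the respective records.
#' @param extra Named character vector of unmodeled attributes.
#' @return A list of class `kgml_pathway`.
#' @export
kgml_pathway <- function(name, org = "", number = "", title = "",
                         entries = list(), relations = list(),
                         reactions = list(), extra = character()) {
  structure(list(name = name, org = org, number = number, title = title,
                 entries = entries, relations = relations,
                 reactions = reactions, extra = extra),
            class = "kgml_pathway")
}

#' @export
print.kgml_pathway <- function(x, ...) {
  cat("<kgml_pathway> ", x$name, if (nzchar(x$title)) paste0(" (", x$title, ")"),
      "\n  entries: ", length(x$entries),
      "  relations: ", length(x$relations),
      "  reactions: ", length(x$reactions), "\n", sep = "")
  invisible(x)
}

# id -> position index over doc entries
entry_index <- function(doc) {
  ids <- vapply(doc$entries, function(e) e$id, integer(1))
  stats::setNames(seq_along(ids), ids)
}

get_entry <- function(doc, id) {
  idx <- entry_index(doc)[as.character(id)]
  if (is.na(idx)) NULL else doc$entries[[idx]]
}

# -- parsing ------------------------------------------------------------------

split_ws <- function(x) {
  if (is.na(x) || !nzchar(x)) character() else strsplit(trimws(x), "\\s+")[[1]]
}

# attributes of `node` except those in `known`, as a named character vector
extra_attrs <- function(node, known) {
  at <- xml2::xml_attrs(node)
  at[setdiff(names(at), known)]
}

#' Parse a KGML pathway document
#'
#' Reads a KGML (KEGG Markup Language) XML file into a [kgml_pathway()]
#' object. Space-separated multi-identifier `name` attributes are split into
#' vectors at parse time; unknown attributes are retained so that
#' [write_kgml()] round-trips losslessly. Reaction modifier sets are derived
#' from entries whose `reaction` attribute names the reaction.
#'
#' @param source Path to a KGML file, a URL-less connection, or a string of
#'   XML (anything [xml2::read_xml()] accepts).
#' @return A [kgml_pathway()] object.
#' @export
#' @examples
#' xml <- paste0('<pathway name="path:syn00001" org="syn" number="00001" ',
#'               'title="demo"><entry id="1" name="cpd:C00031" ',
#'               'type="compound"/></pathway>')
#' doc <- parse_kgml(xml)
#' length(doc$entries)
parse_kgml <- function(source) {
  x <- tryCatch(xml2::read_xml(source),
                error = function(e) stop("KGML parse error: ",
                                         conditionMessage(e), call. = FALSE))
  if (xml2::xml_name(x) != "pathway")
    stop("KGML schema error: root element is <", xml2::xml_name(x),
         ">, expected <pathway>", call. = FALSE)

  pa <- function(node, a) xml2::xml_attr(node, a)

  entries <- lapply(xml2::xml_find_all(x, "./entry"), function(e) {
    id <- pa(e, "id"); ty <- pa(e, "type")
    if (is.na(id)) stop("KGML schema error: <entry> without id", call. = FALSE)
    if (is.na(ty)) stop("KGML schema error: <entry id=\"", id,
                        "\"> without type", call. = FALSE)
    g <- xml2::xml_find_first(e, "./graphics")
    graphics <- if (inherits(g, "xml_node")) {
      kgml_graphics(label = pa(g, "name"), bgcolor = pa(g, "bgcolor"),
                    fgcolor = pa(g, "fgcolor"),
                    x = as.numeric(pa(g, "x")), y = as.numeric(pa(g, "y")),
                    width = as.numeric(pa(g, "width")),
                    height = as.numeric(pa(g, "height")),
                    shape = pa(g, "type"),
                    extra = extra_attrs(g, c("name", "bgcolor", "fgcolor",
                                             "x", "y", "width", "height",
                                             "type")))
    } else NULL
    comp <- as.integer(xml2::xml_attr(xml2::xml_find_all(e, "./component"), "id"))
    kgml_entry(id = as.integer(id), names = split_ws(pa(e, "name")),
               etype = ty, reaction_attr = split_ws(pa(e, "reaction")),
               graphics = graphics, components = comp,
               extra = extra_attrs(e, c("id", "name", "type", "reaction")))
  })

  relations <- lapply(xml2::xml_find_all(x, "./relation"), function(r) {
    subtypes <- lapply(xml2::xml_find_all(r, "./subtype"), function(s)
      list(name = pa(s, "name"), value = pa(s, "value")))
    kgml_relation(entry1 = as.integer(pa(r, "entry1")),
                  entry2 = as.integer(pa(r, "entry2")),
                  rtype = pa(r, "type"), subtypes = subtypes,
                  extra = extra_attrs(r, c("entry1", "entry2", "type")))
  })

  parse_part <- function(p) {
    st <- pa(p, "stoichiometry")
    kgml_participant(entry_id = as.integer(pa(p, "id")),
                     kegg_id = pa(p, "name"),
                     stoichiometry = if (is.na(st)) 1 else as.numeric(st),
                     symbolic_coeff = pa(p, "symbolic"))
  }
  reactions <- lapply(xml2::xml_find_all(x, "./reaction"), function(r) {
    kgml_reaction(ids = split_ws(pa(r, "name")), rtype = pa(r, "type"),
                  substrates = lapply(xml2::xml_find_all(r, "./substrate"),
                                      parse_part),
                  products = lapply(xml2::xml_find_all(r, "./product"),
                                    parse_part),
                  extra = extra_attrs(r, c("id", "name", "type")))
  })

  doc <- kgml_pathway(name = pa(x, "name"), org = pa(x, "org"),
                      number = pa(x, "number"), title = pa(x, "title"),
                      entries = entries, relations = relations,
                      reactions = reactions,
                      extra = extra_attrs(x, c("name", "org", "number",
                                               "title")))
  rewire_modifiers(doc)
}

# modifiers := entries whose reaction attribute names one of rx$ids
rewire_modifiers <- function(doc) {
  doc$reactions <- lapply(doc$reactions, function(rx) {
    mods <- vapply(doc$entries, function(e)
      if (length(intersect(e$reaction_attr, rx$ids))) e$id else NA_integer_,
      integer(1))
    rx$modifiers <- sort(mods[!is.na(mods)])
    rx
  })
  doc
}

#' Validate the structural integrity of a pathway document
#'
#' Reports duplicate entry ids, dangling relation endpoints, dangling
#' reaction participants and groups without components. Findings, not
#' exceptions: an empty result means the document is structurally sound.
#'
#' @param doc A [kgml_pathway()].
#' @return A tibble with columns `severity`, `element`, `message`.
#' @export
validate_doc <- function(doc) {
  out <- list()
  add <- function(severity, element, message)
    out[[length(out) + 1L]] <<- list(severity = severity, element = element,
                                     message = message)
  ids <- vapply(doc$entries, function(e) e$id, integer(1))
  for (d in unique(ids[duplicated(ids)]))
    add("error", paste0("entry:", d), paste("duplicate entry id", d))
  known <- as.character(ids)
  for (i in seq_along(doc$relations)) {
    r <- doc$relations[[i]]
    for (ep in c(r$entry1, r$entry2))
      if (!as.character(ep) %in% known)
        add("error", paste0("relation:", i),
            paste("relation endpoint references nonexistent entry id", ep))
  }
  for (i in seq_along(doc$reactions)) {
    rx <- doc$reactions[[i]]
    for (p in c(rx$substrates, rx$products))
      if (!is.na(p$entry_id) && !as.character(p$entry_id) %in% known)
        add("error", paste0("reaction:", paste(rx$ids, collapse = " ")),
            paste("participant references nonexistent entry id", p$entry_id))
  }
  for (e in doc$entries) {
    if (e$etype == "group" && length(e$components) == 0L)
      add("error", paste0("entry:", e$id), "group entry has no components")
    if (e$etype == "group")
      for (c in e$components)
        if (!as.character(c) %in% known)
          add("error", paste0("entry:", e$id),
              paste("group component references nonexistent entry id", c))
  }
  if (length(out) == 0L)
    return(tibble::tibble(severity = character(), element = character(),
                          message = character()))
  tibble::tibble(severity = vapply(out, `[[`, "", "severity"),
                 element = vapply(out, `[[`, "", "element"),
                 message = vapply(out, `[[`, "", "message"))
}

# -- serialization ------------------------------------------------------------

set_attrs <- function(node, attrs) {
  attrs <- attrs[!vapply(attrs, function(v) is.null(v) || is.na(v), logical(1))]
  for (nm in names(attrs)) xml2::xml_set_attr(node, nm, as.character(attrs[[nm]]))
  node
}

num_attr <- function(x) {
  if (is.null(x) || is.na(x)) return(NA_character_)
  # integers print without trailing .0 so round-trips are byte-stable
  if (x == trunc(x)) format(as.integer(x)) else format(x)
}

#' Write a pathway document as KGML
#'
#' Inverse of [parse_kgml()]: all modeled fields (including the extra
#' attribute side maps and the stoichiometry dialect extension on completed
#' reactions) serialize so that a re-parse is field-equal to `doc`.
#'
#' @param doc A [kgml_pathway()].
#' @param sink File path to write to.
#' @return `sink`, invisibly.
#' @export
write_kgml <- function(doc, sink) {
  as_xml_kgml <- function(doc) {
    x <- xml2::xml_new_root("pathway")
    set_attrs(x, c(list(name = doc$name, org = doc$org, number = doc$number,
                        title = doc$title), as.list(doc$extra)))
    for (e in doc$entries) {
      en <- xml2::xml_add_child(x, "entry")
      set_attrs(en, c(list(id = e$id,
                           name = if (length(e$names)) paste(e$names, collapse = " "),
                           type = e$etype,
                           reaction = if (length(e$reaction_attr))
                             paste(e$reaction_attr, collapse = " ")),
                      as.list(e$extra)))
      if (!is.null(e$graphics)) {
        g <- e$graphics
        gn <- xml2::xml_add_child(en, "graphics")
        set_attrs(gn, c(list(name = g$label, fgcolor = g$fgcolor,
                             bgcolor = g$bgcolor, type = g$shape,
                             x = num_attr(g$x), y = num_attr(g$y),
                             width = num_attr(g$width),
                             height = num_attr(g$height)),
                        as.list(g$extra)))
      }
      for (cid in e$components)
        set_attrs(xml2::xml_add_child(en, "component"), list(id = cid))
    }
    for (r in doc$relations) {
      rn <- xml2::xml_add_child(x, "relation")
      set_attrs(rn, c(list(entry1 = r$entry1, entry2 = r$entry2,
                           type = r$rtype), as.list(r$extra)))
      for (st in r$subtypes)
        set_attrs(xml2::xml_add_child(rn, "subtype"),
                  list(name = st$name, value = st$value))
    }
    for (rx in doc$reactions) {
      xn <- xml2::xml_add_child(x, "reaction")
      set_attrs(xn, c(list(name = paste(rx$ids, collapse = " "),
                           type = rx$rtype), as.list(rx$extra)))
      emit_part <- function(tag, p) {
        pn <- xml2::xml_add_child(xn, tag)
        set_attrs(pn, list(id = p$entry_id, name = p$kegg_id,
                           stoichiometry = if (p$stoichiometry != 1)
                             num_attr(p$stoichiometry),
                           symbolic = p$symbolic_coeff))
      }
      for (p in rx$substrates) emit_part("substrate", p)
      for (p in rx$products) emit_part("product", p)
    }
    x
  }
  x <- as_xml_kgml(doc)
  xml2::write_xml(x, sink)
  invisible(sink)
}
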