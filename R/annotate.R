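# Machine-readable cross-references (MIRIAM URNs, controlled-vocabulary
# terms with biology qualifiers) and human-readable note blocks, shared by
# the SBML and BioPAX exporters. Annotation is a pure function of
# (element, store): repeated calls are byte-identical.

MIRIAM_REGISTRY <- c(
  "kegg.compound", "kegg.genes", "kegg.reaction", "kegg.pathway",
  "kegg.drug", "kegg.glycan", "kegg.orthology", "ncbigene", "uniprot",
  "ensembl", "omim", "chebi", "hgnc", "go", "pubchem.compound", "3dmet",
  "taxonomy", "ec-code", "drugbank", "pdbechem", "glycomedb", "lipidbank",
  "obo.mi", "obo.mod", "biomodels.sbo")

# xref database label (store dialect) -> MIRIAM collection
XREF_COLLECTION <- c(
  "NCBI-GeneID" = "ncbigene", "UniProt" = "uniprot", "Ensembl" = "ensembl",
  "OMIM" = "omim", "HGNC" = "hgnc", "GO" = "go", "ChEBI" = "chebi",
  "PubChem" = "pubchem.compound", "3DMET" = "3dmet", "DrugBank" = "drugbank",
  "PDBeChem" = "pdbechem", "GlycomeDB" = "glycomedb",
  "LipidBank" = "lipidbank")

CV_QUALIFIERS <- c("IS", "HAS_PART", "IS_ENCODED_BY", "IS_DESCRIBED_BY",
                   "HAS_VERSION", "OCCURS_IN")

#' Build a MIRIAM URN
#'
#' @param collection Registry collection name (supported subset; see
#'   `MIRIAM_REGISTRY` in the package source).
#' @param id Identifier within the collection; percent-encoded.
#' @return A string `urn:miriam:<collection>:<encoded id>`.
#' @export
#' @examples
#' miriam_urn("kegg.compound", "C00031")
miriam_urn <- function(collection, id) {
  if (!collection %in% MIRIAM_REGISTRY)
    stop("registry error: unknown MIRIAM collection '", collection, "'",
         call. = FALSE)
  paste0("urn:miriam:", collection, ":",
         utils::URLencode(as.character(id), reserved = TRUE))
}

# KEGG identifier -> (collection, bare id) or NULL for unknown shapes
kegg_id_collection <- function(id) {
  pre <- sub(":.*$", "", id)
  rest <- sub("^[^:]*:", "", id)
  switch(pre,
         cpd = list(collection = "kegg.compound", id = rest),
         gl = list(collection = "kegg.glycan", id = rest),
         dr = list(collection = "kegg.drug", id = rest),
         rn = list(collection = "kegg.reaction", id = rest),
         path = list(collection = "kegg.pathway", id = rest),
         ko = list(collection = "kegg.orthology", id = rest),
         ec = list(collection = "ec-code", id = rest),
         # organism-prefixed gene identifiers keep the prefix
         list(collection = "kegg.genes", id = id))
}

kegg_urn <- function(id) {
  kc <- kegg_id_collection(id)
  miriam_urn(kc$collection, kc$id)
}

cv_term <- function(qualifier, urns) {
  qualifier <- match.arg(qualifier, CV_QUALIFIERS)
  stopifnot(length(urns) >= 1L)
  list(qualifier = qualifier, urns = unname(urns))
}

# all xref URNs for one KEGG identifier, grouped per collection
xref_urns_for_id <- function(id, store, etype) {
  rec <- if (etype %in% c("compound", "map"))
    store_lookup(store, "compound", id)
  else store_lookup(store, "gene", id)
  if (is.null(rec) || is.null(rec$xrefs) || length(rec$xrefs) == 0L)
    return(list())
  out <- list()
  for (db in sort(names(rec$xrefs))) {
    coll <- XREF_COLLECTION[[db]]
    if (is.null(coll) || is.na(coll)) next        # e.g. CAS: notes only
    out[[coll]] <- sort(vapply(rec$xrefs[[db]], function(v)
      miriam_urn(coll, v), ""))
  }
  # EC numbers of gene records resolve to ec-code
  if (!is.null(rec$ec_numbers) && length(rec$ec_numbers))
    out[["ec-code"]] <- sort(vapply(rec$ec_numbers, function(v)
      miriam_urn("ec-code", v), ""))
  out[sort(names(out))]
}

#' Controlled-vocabulary terms for a KGML entry
#'
#' One `IS` term per KEGG identifier for single-identity entries;
#' `HAS_VERSION` terms instead when the entry carries several gene
#' identifiers (a merged multi-gene node is not identical to any single
#' member); `HAS_PART` for group entries, enumerating the member entries'
#' identifiers. Cross-reference URNs from the store are appended grouped
#' per collection. Ordering is deterministic.
#'
#' @param entry A [kgml_entry()].
#' @param store A `resource_store`.
#' @param doc The containing [kgml_pathway()] (needed to resolve group
#'   components); may be `NULL` for non-group entries.
#' @return A list of CV terms (`list(qualifier, urns)`).
#' @export
cv_terms_for_entry <- function(entry, store, doc = NULL) {
  terms <- list()
  if (entry$etype == "group") {
    urns <- character()
    if (!is.null(doc)) {
      for (cid in entry$components) {
        ce <- get_entry(doc, cid)
        if (!is.null(ce))
          urns <- c(urns, vapply(ce$names, kegg_urn, ""))
      }
    }
    if (length(urns))
      terms[[length(terms) + 1L]] <- cv_term("HAS_PART", sort(unique(urns)))
    return(terms)
  }
  multi_gene <- length(entry$names) > 1L &&
    entry$etype %in% c("gene", "enzyme", "ortholog")
  qual <- if (multi_gene) "HAS_VERSION" else "IS"
  for (nm in entry$names)
    terms[[length(terms) + 1L]] <- cv_term(qual, kegg_urn(nm))
  xr <- list()
  for (nm in entry$names) {
    for (coll_urns in list(xref_urns_for_id(nm, store, entry$etype))) {
      for (coll in names(coll_urns))
        xr[[coll]] <- sort(unique(c(xr[[coll]], coll_urns[[coll]])))
    }
  }
  for (coll in sort(names(xr)))
    terms[[length(terms) + 1L]] <- cv_term(qual, xr[[coll]])
  terms
}

#' Human-readable note block for an entry or reaction
#'
#' Compounds carry their synonyms, chemical formula and molecular weight;
#' reactions carry the store definition, the equation text, the list of
#' other pathways the reaction occurs in (when known) and the formatted
#' atom-balance report. Elements absent from the store fall back to a bare
#' KEGG link. Field ordering is deterministic.
#'
#' @param element A [kgml_entry()] or [kgml_reaction()].
#' @param store A `resource_store`.
#' @param balance Optional `balance_report` for reactions.
#' @return A list of class `note_block` with `description`, `synonyms`,
#'   `formula`, `mol_weight`, `links` and an ordered `extra` map.
#' @export
notes_for <- function(element, store, balance = NULL) {
  nb <- list(description = NA_character_, synonyms = character(),
             formula = NA_character_, mol_weight = NA_real_,
             links = character(), extra = list())
  if (inherits(element, "kgml_reaction")) {
    rec <- store$reactions[[element$ids[1]]]
    if (!is.null(rec)) {
      if (nzchar(rec$definition)) nb$description <- rec$definition
      nb$extra[["equation"]] <- rec$equation
      if (length(rec$ec_numbers))
        nb$extra[["enzymes"]] <- paste(rec$ec_numbers, collapse = " ")
    }
    nb$links <- paste0("https://www.kegg.jp/entry/",
                       sub("^rn:", "", element$ids[1]))
    if (!is.null(balance))
      nb$extra[["atom-check"]] <- format_balance_report(balance)
    return(structure(nb, class = "note_block"))
  }
  # entry
  for (nm in element$names) {
    rec <- if (element$etype %in% c("compound", "other", "map"))
      store_lookup(store, "compound", nm)
    else store_lookup(store, "gene", nm)
    if (is.null(rec)) next
    if (!is.null(rec$names) && length(rec$names))
      nb$synonyms <- c(nb$synonyms, rec$names)
    if (!is.null(rec$symbols) && length(rec$symbols))
      nb$synonyms <- c(nb$synonyms, rec$symbols)
    if (!is.null(rec$description) && nzchar(rec$description) &&
        is.na(nb$description))
      nb$description <- rec$description
    if (!is.null(rec$formula) && !is.na(rec$formula) && is.na(nb$formula))
      nb$formula <- rec$formula
    if (!is.null(rec$mol_weight) && !is.na(rec$mol_weight) &&
        is.na(nb$mol_weight))
      nb$mol_weight <- rec$mol_weight
    if (!is.null(rec$xrefs) && "CAS" %in% names(rec$xrefs))
      nb$extra[["cas"]] <- paste(rec$xrefs[["CAS"]], collapse = " ")
  }
  nb$synonyms <- unique(nb$synonyms)
  nb$links <- vapply(element$names, function(nm)
    paste0("https://www.kegg.jp/entry/", sub("^[a-z]+:", "", nm)), "",
    USE.NAMES = FALSE)
  structure(nb, class = "note_block")
}

# render a note block as the XHTML fragment SBML notes require
note_xhtml_body <- function(nb, title = NULL) {
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  p <- character()
  if (!is.null(title)) p <- c(p, paste0("<p><b>", esc(title), "</b></p>"))
  if (!is.na(nb$description))
    p <- c(p, paste0("<p>", esc(nb$description), "</p>"))
  if (length(nb$synonyms))
    p <- c(p, paste0("<p>Synonyms: ",
                     esc(paste(nb$synonyms, collapse = "; ")), "</p>"))
  if (!is.na(nb$formula))
    p <- c(p, paste0("<p>Formula: ", esc(nb$formula), "</p>"))
  if (!is.na(nb$mol_weight))
    p <- c(p, paste0("<p>Molecular weight: ", format(nb$mol_weight),
                     " g/mol</p>"))
  for (key in names(nb$extra))
    p <- c(p, paste0("<p>", esc(key), ":</p><pre>", esc(nb$extra[[key]]),
                     "</pre>"))
  for (l in nb$links)
    p <- c(p, paste0("<p><a href=\"", esc(l), "\">", esc(l), "</a></p>"))
  paste0("<body xmlns=\"http://www.w3.org/1999/xhtml\">",
         paste(p, collapse = ""), "</body>")
}
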