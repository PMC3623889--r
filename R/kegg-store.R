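# Offline resource store: keyed reaction/compound/gene records plus an
# identifier alias table, standing in for the KEGG API. The on-disk format
# mirrors KEGG flat-file style (one block per record, keyed lines, blocks
# terminated by "///") so real dumps can later be ingested.

#' Parse a reaction equation string
#'
#' Grammar: the two sides split on the connector (`<=>` reversible, `=>`
#' irreversible); participants split on `" + "`; each participant is an
#' optional coefficient — an integer, or a parenthesized symbolic expression
#' such as `(n+1)` — followed by an identifier. Symbolic coefficients are
#' evaluated at n = 1 for their numeric value and kept verbatim.
#'
#' @param text Equation, e.g. `"2 cpd:C00001 + cpd:C00002 => cpd:C00003"`.
#' @return List with `substrates`, `products` (each a list of
#'   `list(id, coeff, symbolic)`) and `reversible`.
#' @export
parse_equation <- function(text) {
  reversible <- grepl("<=>", text, fixed = TRUE)
  sides <- strsplit(text, if (reversible) "<=>" else "=>", fixed = TRUE)[[1]]
  if (length(sides) != 2L)
    stop("equation does not split into two sides: ", text, call. = FALSE)
  parse_side <- function(s) {
    parts <- strsplit(s, " + ", fixed = TRUE)[[1]]
    parts <- trimws(parts)
    parts <- parts[nzchar(parts)]
    if (length(parts) == 0L)
      stop("empty equation side in: ", text, call. = FALSE)
    lapply(parts, function(p) {
      toks <- strsplit(p, "\\s+")[[1]]
      if (length(toks) == 1L)
        return(list(id = toks, coeff = 1, symbolic = NA_character_))
      if (length(toks) != 2L)
        stop("cannot parse equation participant '", p, "'", call. = FALSE)
      co <- toks[1]
      if (grepl("^[0-9]+$", co))
        return(list(id = toks[2], coeff = as.numeric(co),
                    symbolic = NA_character_))
      if (grepl("^\\(.*\\)$", co)) {
        sym <- substr(co, 2, nchar(co) - 1L)
        return(list(id = toks[2], coeff = eval_symbolic_coeff(sym),
                    symbolic = sym))
      }
      stop("cannot parse coefficient '", co, "' in equation participant '",
           p, "'", call. = FALSE)
    })
  }
  list(substrates = parse_side(sides[1]), products = parse_side(sides[2]),
       reversible = reversible)
}

# value of a symbolic coefficient like "n", "n+1", "2n" at n = 1
eval_symbolic_coeff <- function(sym) {
  s <- gsub(" ", "", sym)
  if (!grepl("^[0-9n+*-]+$", s))
    stop("unsupported symbolic coefficient '", sym, "'", call. = FALSE)
  s <- gsub("([0-9])n", "\\1*n", s)
  v <- eval(parse(text = s), envir = list(n = 1))
  if (!is.finite(v) || v <= 0)
    stop("symbolic coefficient '", sym, "' is not positive at n=1",
         call. = FALSE)
  v
}

#' @rdname load_store
#' @param reactions,compounds,genes Named lists of records.
#' @param aliases Named character vector mapping alias id -> canonical id.
#' @export
resource_store <- function(reactions = list(), compounds = list(),
                           genes = list(), aliases = character()) {
  structure(list(reactions = reactions, compounds = compounds,
                 genes = genes, aliases = aliases),
            class = "resource_store")
}

#' @export
print.resource_store <- function(x, ...) {
  cat("<resource_store> reactions: ", length(x$reactions),
      "  compounds: ", length(x$compounds),
      "  genes: ", length(x$genes),
      "  aliases: ", length(x$aliases), "\n", sep = "")
  invisible(x)
}

reaction_record <- function(id, equation, reversible, ec_numbers = character(),
                            definition = "") {
  eq <- parse_equation(equation)
  if (eq$reversible != reversible)
    stop("reaction ", id, ": reversibility flag disagrees with connector",
         call. = FALSE)
  list(id = id, equation = equation, reversible = reversible,
       ec_numbers = as.character(ec_numbers), definition = definition)
}

compound_record <- function(id, names = character(), formula = NA_character_,
                            mol_weight = NA_real_, xrefs = list()) {
  list(id = id, names = as.character(names), formula = formula,
       mol_weight = mol_weight, xrefs = xrefs)
}

gene_record <- function(id, symbols = character(), description = "",
                        ec_numbers = character(), xrefs = list()) {
  list(id = id, symbols = as.character(symbols), description = description,
       ec_numbers = as.character(ec_numbers), xrefs = xrefs)
}

# -- flat-file parsing --------------------------------------------------------

# split a flat file into blocks of keyed lines; returns list of named lists
# (values are character vectors, repeated keys append)
read_blocks <- function(path) {
  lines <- readLines(path, warn = FALSE)
  blocks <- list()
  cur <- list()
  for (ln in lines) {
    if (grepl("^///", ln)) {
      if (length(cur)) blocks[[length(blocks) + 1L]] <- cur
      cur <- list()
      next
    }
    if (!nzchar(trimws(ln))) next
    m <- regmatches(ln, regexec("^(\\S+)\\s+(.*)$", ln))[[1]]
    if (length(m) != 3L)
      stop("malformed record line in ", path, ": '", ln, "'", call. = FALSE)
    key <- m[2]; val <- trimws(m[3])
    cur[[key]] <- c(cur[[key]], val)
  }
  if (length(cur)) blocks[[length(blocks) + 1L]] <- cur
  blocks
}

field1 <- function(block, key, default = NA_character_) {
  v <- block[[key]]
  if (is.null(v)) default else v[1]
}

parse_dblinks <- function(block) {
  xr <- list()
  for (ln in block[["DBLINKS"]]) {
    m <- regmatches(ln, regexec("^([^:]+):\\s*(.*)$", ln))[[1]]
    if (length(m) == 3L)
      xr[[trimws(m[2])]] <- c(xr[[trimws(m[2])]],
                              strsplit(trimws(m[3]), "\\s+")[[1]])
  }
  xr
}

#' Load or construct an offline resource store
#'
#' `load_store()` reads a store directory containing `reactions.txt`,
#' `compounds.txt`, `genes.txt` (KEGG flat-file style blocks terminated by
#' `///`) and `aliases.tsv` (two columns, alias then canonical compound id).
#' The alias table is closed under resolution and referential integrity of
#' every stored equation is checked. `resource_store()` builds one in code.
#'
#' @param path Directory containing the record files.
#' @return A `resource_store` object.
#' @export
load_store <- function(path) {
  for (f in c("reactions.txt", "compounds.txt", "genes.txt", "aliases.tsv"))
    if (!file.exists(file.path(path, f)))
      stop("store load error: missing file '", f, "' in ", path,
           call. = FALSE)

  al_lines <- readLines(file.path(path, "aliases.tsv"), warn = FALSE)
  al_lines <- al_lines[nzchar(trimws(al_lines))]
  aliases <- character()
  for (ln in al_lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) != 2L)
      stop("malformed alias line: '", ln, "'", call. = FALSE)
    aliases[[f[1]]] <- f[2]
  }
  # close under resolution; reject cycles
  for (a in names(aliases)) {
    seen <- a; cur <- aliases[[a]]
    while (cur %in% names(aliases)) {
      if (cur %in% seen)
        stop("alias cycle involving '", a, "'", call. = FALSE)
      seen <- c(seen, cur)
      cur <- aliases[[cur]]
    }
    aliases[[a]] <- cur
  }

  compounds <- list()
  for (b in read_blocks(file.path(path, "compounds.txt"))) {
    id <- field1(b, "ENTRY")
    nm <- field1(b, "NAME", "")
    compounds[[id]] <- compound_record(
      id = id,
      names = if (nzchar(nm)) trimws(strsplit(nm, ";", fixed = TRUE)[[1]])
              else character(),
      formula = field1(b, "FORMULA"),
      mol_weight = as.numeric(field1(b, "MOL_WEIGHT")),
      xrefs = parse_dblinks(b))
  }

  genes <- list()
  for (b in read_blocks(file.path(path, "genes.txt"))) {
    id <- field1(b, "ENTRY")
    sy <- field1(b, "SYMBOL", "")
    ec <- field1(b, "EC", "")
    genes[[id]] <- gene_record(
      id = id,
      symbols = if (nzchar(sy)) trimws(strsplit(sy, ";", fixed = TRUE)[[1]])
                else character(),
      description = field1(b, "DESCRIPTION", ""),
      ec_numbers = if (nzchar(ec)) strsplit(ec, "\\s+")[[1]] else character(),
      xrefs = parse_dblinks(b))
  }

  reactions <- list()
  for (b in read_blocks(file.path(path, "reactions.txt"))) {
    id <- field1(b, "ENTRY")
    ec <- field1(b, "ENZYME", "")
    reactions[[id]] <- reaction_record(
      id = id,
      equation = field1(b, "EQUATION"),
      reversible = identical(field1(b, "REVERSIBLE", "false"), "true"),
      ec_numbers = if (nzchar(ec)) strsplit(ec, "\\s+")[[1]] else character(),
      definition = field1(b, "DEFINITION", ""))
  }

  store <- resource_store(reactions = reactions, compounds = compounds,
                          genes = genes, aliases = aliases)
  # referential integrity: every equation id resolves
  for (r in store$reactions) {
    eq <- parse_equation(r$equation)
    for (p in c(eq$substrates, eq$products)) {
      cid <- canonical_compound_id(store, p$id)
      if (is.null(store$compounds[[cid]]))
        stop("store integrity error: reaction ", r$id,
             " references unknown compound '", p$id, "'", call. = FALSE)
    }
  }
  store
}

#' Write a resource store to a directory
#'
#' Inverse of [load_store()]; emits the flat-file layout the loader reads.
#'
#' @param store A `resource_store`.
#' @param path Output directory (created if absent).
#' @return `path`, invisibly.
#' @export
write_store <- function(store, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  pad <- function(k) formatC(k, width = 12, flag = "-")
  dblink_lines <- function(xrefs)
    unlist(lapply(names(xrefs), function(db)
      paste0(pad("DBLINKS"), db, ": ", paste(xrefs[[db]], collapse = " "))))

  con <- file(file.path(path, "compounds.txt"), "w")
  for (c in store$compounds) {
    writeLines(paste0(pad("ENTRY"), c$id), con)
    if (length(c$names))
      writeLines(paste0(pad("NAME"), paste(c$names, collapse = "; ")), con)
    if (!is.na(c$formula))
      writeLines(paste0(pad("FORMULA"), c$formula), con)
    if (!is.na(c$mol_weight))
      writeLines(paste0(pad("MOL_WEIGHT"), format(c$mol_weight)), con)
    writeLines(c(dblink_lines(c$xrefs), "///"), con)
  }
  close(con)

  con <- file(file.path(path, "genes.txt"), "w")
  for (g in store$genes) {
    writeLines(paste0(pad("ENTRY"), g$id), con)
    if (length(g$symbols))
      writeLines(paste0(pad("SYMBOL"), paste(g$symbols, collapse = "; ")), con)
    if (nzchar(g$description))
      writeLines(paste0(pad("DESCRIPTION"), g$description), con)
    if (length(g$ec_numbers))
      writeLines(paste0(pad("EC"), paste(g$ec_numbers, collapse = " ")), con)
    writeLines(c(dblink_lines(g$xrefs), "///"), con)
  }
  close(con)

  con <- file(file.path(path, "reactions.txt"), "w")
  for (r in store$reactions) {
    writeLines(paste0(pad("ENTRY"), r$id), con)
    if (nzchar(r$definition))
      writeLines(paste0(pad("DEFINITION"), r$definition), con)
    writeLines(paste0(pad("EQUATION"), r$equation), con)
    if (length(r$ec_numbers))
      writeLines(paste0(pad("ENZYME"), paste(r$ec_numbers, collapse = " ")), con)
    writeLines(paste0(pad("REVERSIBLE"), if (r$reversible) "true" else "false"),
               con)
    writeLines("///", con)
  }
  close(con)

  writeLines(if (length(store$aliases))
               paste0(names(store$aliases), "\t", store$aliases)
             else character(),
             file.path(path, "aliases.tsv"))
  invisible(path)
}

#' Look up a record in the resource store
#'
#' Compound lookups transparently follow the alias table to the canonical
#' record (so a glycan or drug synonym retrieves its KEGG COMPOUND record).
#' Absent identifiers return `NULL`, never an error.
#'
#' @param store A `resource_store`.
#' @param namespace One of `"reaction"`, `"compound"`, `"gene"`.
#' @param id Identifier to look up.
#' @return The record (a list), or `NULL` when absent.
#' @export
store_lookup <- function(store, namespace, id) {
  namespace <- match.arg(namespace, c("reaction", "compound", "gene"))
  switch(namespace,
         reaction = store$reactions[[id]],
         gene = store$genes[[id]],
         compound = store$compounds[[canonical_compound_id(store, id)]])
}

#' Resolve an identifier to its canonical KEGG COMPOUND synonym
#'
#' One substance may carry identifiers in several KEGG sub-databases
#' (COMPOUND, DRUG, GLYCAN); formulas and reaction equations use the
#' COMPOUND one. Returns the COMPOUND synonym when the alias table has one,
#' else the input unchanged. Idempotent.
#'
#' @inheritParams store_lookup
#' @return A character identifier.
#' @export
canonical_compound_id <- function(store, id) {
  if (id %in% names(store$aliases)) store$aliases[[id]] else id
}
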