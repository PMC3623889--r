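# Chemical formula parsing and stoichiometry-weighted atom balance.
#
# KEGG formulas are plain Hill-style element strings, occasionally with a
# generic substituent R (any side chain) or a parenthesized repeat unit
# followed by n (polymers). Either makes an exact balance undecidable, so
# such reactions are reported as indeterminate rather than guessed at.

# valid IUPAC element symbols (sufficient superset for biochemistry)
ELEMENT_SYMBOLS <- c(
  "H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne", "Na", "Mg", "Al",
  "Si", "P", "S", "Cl", "Ar", "K", "Ca", "Sc", "Ti", "V", "Cr", "Mn", "Fe",
  "Co", "Ni", "Cu", "Zn", "Ga", "Ge", "As", "Se", "Br", "Kr", "Rb", "Sr",
  "Mo", "Ag", "Cd", "Sn", "I", "Te", "Ba", "W", "Pt", "Au", "Hg", "Pb")

# monoisotopic-free average masses for the elements the generator uses
ATOMIC_MASS <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, P = 30.974,
                 S = 32.06, Na = 22.99, K = 39.098, Cl = 35.45, Fe = 55.845,
                 Mg = 24.305, Ca = 40.078, Zn = 65.38, Se = 78.971, I = 126.9)

#' Parse a chemical formula string
#'
#' Accepts the KEGG formula dialect: element symbols with optional integer
#' counts (`C10H16N5O13P3`), one level of parenthesized groups with a
#' multiplier (`Ca(OH)2`), a polymeric repeat unit — parenthesized group
#' followed by `n` (`(C6H10O5)n`, counted once and flagged) — a generic
#' substituent `R` (optionally numbered `R1`, `R2`; flagged), and trailing
#' charge tokens (`+`, `-`, `2-`), which are stripped from atom counting
#' and flagged.
#'
#' @param text Non-empty formula string.
#' @return A list of class `chem_formula` with fields `counts` (named
#'   numeric, element -> count), `has_generic`, `has_polymeric`,
#'   `charge_stripped` and `raw`.
#' @export
#' @examples
#' parse_formula("H2O")$counts
#' parse_formula("C2H4NO2R")$has_generic
parse_formula <- function(text) {
  if (is.null(text) || is.na(text) || !nzchar(text))
    stop("formula error: empty formula string", call. = FALSE)
  counts <- numeric()
  has_generic <- FALSE
  has_polymeric <- FALSE
  charge_stripped <- FALSE
  add <- function(el, k) {
    counts[el] <<- if (el %in% names(counts)) counts[[el]] + k else k
  }
  i <- 1L; nch <- nchar(text)
  peek <- function() if (i <= nch) substr(text, i, i) else ""
  take_int <- function(default = 1) {
    j <- i
    while (j <= nch && grepl("[0-9]", substr(text, j, j))) j <- j + 1L
    if (j == i) return(default)
    v <- as.numeric(substr(text, i, j - 1L))
    i <<- j
    v
  }
  take_element <- function() {
    two <- substr(text, i, min(i + 1L, nch))
    if (nchar(two) == 2L && two %in% ELEMENT_SYMBOLS &&
        grepl("^[A-Z][a-z]$", two)) {
      i <<- i + 2L
      return(two)
    }
    one <- substr(text, i, i)
    if (one %in% ELEMENT_SYMBOLS) {
      i <<- i + 1L
      return(one)
    }
    stop("formula error at offset ", i, " in '", text,
         "': unknown symbol '", one, "'", call. = FALSE)
  }
  scale_into <- function(group, k, mult = 1) {
    for (el in names(group)) add(el, group[[el]] * k * mult)
  }
  while (i <= nch) {
    ch <- peek()
    if (ch == "R") {
      # generic substituent, optionally numbered
      i <- i + 1L
      take_int()
      has_generic <- TRUE
      next
    }
    if (ch == "(") {
      i <- i + 1L
      group <- numeric()
      while (peek() != ")" && i <= nch) {
        if (peek() == "(")
          stop("formula error at offset ", i, " in '", text,
               "': nested parentheses deeper than one level", call. = FALSE)
        if (peek() == "R") { i <- i + 1L; take_int(); has_generic <- TRUE; next }
        el <- take_element()
        k <- take_int()
        group[el] <- if (el %in% names(group)) group[[el]] + k else k
      }
      if (peek() != ")")
        stop("formula error in '", text, "': unclosed parenthesis",
             call. = FALSE)
      i <- i + 1L
      if (peek() == "n") {
        i <- i + 1L
        has_polymeric <- TRUE
        scale_into(group, 1)      # repeat unit counted once
      } else {
        scale_into(group, take_int())
      }
      next
    }
    if (ch %in% c("+", "-")) {
      i <- i + 1L
      charge_stripped <- TRUE
      next
    }
    if (grepl("[0-9]", ch)) {
      # a digit right before a trailing charge sign (e.g. "2-")
      j <- i
      while (j <= nch && grepl("[0-9]", substr(text, j, j))) j <- j + 1L
      if (j <= nch && substr(text, j, j) %in% c("+", "-")) {
        i <- j + 1L
        charge_stripped <- TRUE
        next
      }
      stop("formula error at offset ", i, " in '", text,
           "': dangling count", call. = FALSE)
    }
    el <- take_element()
    add(el, take_int())
  }
  structure(list(counts = counts[order(names(counts))],
                 has_generic = has_generic, has_polymeric = has_polymeric,
                 charge_stripped = charge_stripped, raw = text),
            class = "chem_formula")
}

# element-count sum of a list of (counts, coeff); returns named numeric
sum_counts <- function(counts_list, coeffs) {
  out <- stats::setNames(numeric(), character())
  for (k in seq_along(counts_list)) {
    cc <- counts_list[[k]]
    for (el in names(cc))
      out[el] <- (if (el %in% names(out)) out[[el]] else 0) +
        cc[[el]] * coeffs[[k]]
  }
  out[order(names(out))]
}

#' Mass of a formula from average atomic masses
#'
#' @param formula A string or `chem_formula`.
#' @return Molecular weight in g/mol.
#' @export
formula_weight <- function(formula) {
  f <- if (inherits(formula, "chem_formula")) formula else parse_formula(formula)
  unknown <- setdiff(names(f$counts), names(ATOMIC_MASS))
  if (length(unknown))
    stop("no atomic mass for element(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  sum(ATOMIC_MASS[names(f$counts)] * f$counts)
}

#' Per-element atom balance of a completed reaction
#'
#' Sums `stoichiometry x formula` over each side and reports the
#' substrate-minus-product difference per element. A reaction is `balanced`
#' iff every difference is zero and no participant is generic, polymeric,
#' symbolically weighted or missing a formula; any of the latter makes the
#' balance `indeterminate` (the count cannot be decided, so no judgment is
#' made); otherwise `unbalanced`.
#'
#' @param rx A completed [kgml_reaction()] (single id, participants with
#'   stoichiometry).
#' @param store A `resource_store` supplying compound formulas.
#' @return A list of class `balance_report` with fields `reaction_id`,
#'   `substrate_atoms`, `product_atoms`, `diff`, `status`,
#'   `missing_formulas`, `charge_stripped`.
#' @export
reaction_atom_diff <- function(rx, store) {
  stopifnot(length(rx$ids) == 1L)
  missing_formulas <- character()
  indeterminate <- FALSE
  charge_stripped <- FALSE
  side_counts <- function(parts) {
    cl <- list(); co <- numeric()
    for (p in parts) {
      if (!is.na(p$symbolic_coeff)) indeterminate <<- TRUE
      rec <- store_lookup(store, "compound", p$kegg_id)
      if (is.null(rec) || is.na(rec$formula)) {
        missing_formulas <<- c(missing_formulas, p$kegg_id)
        next
      }
      f <- parse_formula(rec$formula)
      if (f$has_generic || f$has_polymeric) indeterminate <<- TRUE
      if (f$charge_stripped) charge_stripped <<- TRUE
      cl[[length(cl) + 1L]] <- f$counts
      co[length(co) + 1L] <- p$stoichiometry
    }
    sum_counts(cl, co)
  }
  sub <- side_counts(rx$substrates)
  prod <- side_counts(rx$products)
  els <- sort(union(names(sub), names(prod)))
  diff <- stats::setNames(
    vapply(els, function(el)
      (if (el %in% names(sub)) sub[[el]] else 0) -
      (if (el %in% names(prod)) prod[[el]] else 0), numeric(1)), els)
  diff <- diff[diff != 0]
  status <- if (indeterminate || length(missing_formulas)) "indeterminate"
            else if (length(diff)) "unbalanced" else "balanced"
  structure(list(reaction_id = rx$ids, substrate_atoms = sub,
                 product_atoms = prod, diff = diff, status = status,
                 missing_formulas = unique(missing_formulas),
                 charge_stripped = charge_stripped),
            class = "balance_report")
}

#' @export
print.balance_report <- function(x, ...) {
  cat(format_balance_report(x), "\n")
  invisible(x)
}

#' Render an atom-balance report as stable text
#'
#' The block states the status, both sides' element totals and every nonzero
#' difference, in alphabetical element order so repeated runs are
#' byte-identical. Exporters embed this text verbatim into SBML notes and
#' BioPAX comments; imbalances are never auto-corrected because the actually
#' missing components are unknowable from the equation alone.
#'
#' @param rep A `balance_report`.
#' @return A single character string (lines joined by `\n`).
#' @export
format_balance_report <- function(rep) {
  fmt_counts <- function(cc) {
    if (length(cc) == 0L) return("(none)")
    paste(paste0(names(cc), ":", vapply(cc, num_attr, "")), collapse = " ")
  }
  lines <- c(paste0("Atom balance check for ", rep$reaction_id, ": ",
                    rep$status),
             paste0("  substrate atoms: ", fmt_counts(rep$substrate_atoms)),
             paste0("  product atoms:   ", fmt_counts(rep$product_atoms)))
  if (length(rep$diff))
    lines <- c(lines, paste0("  difference (substrate - product): ",
                             paste(paste0(names(rep$diff),
                                          ifelse(rep$diff > 0, ":+", ":"),
                                          vapply(rep$diff, num_attr, "")),
                                   collapse = " ")))
  if (length(rep$missing_formulas))
    lines <- c(lines, paste0("  missing formulas: ",
                             paste(rep$missing_formulas, collapse = " ")))
  if (rep$status == "indeterminate" && !length(rep$missing_formulas))
    lines <- c(lines,
               "  indeterminate: generic substituent (R) or polymeric/symbolic coefficient present")
  if (isTRUE(rep$charge_stripped))
    lines <- c(lines,
               "  note: charge tokens were stripped before counting (protons not balanced)")
  paste(lines, collapse = "\n")
}

#' Balance reports for all reactions of a document
#'
#' @param doc A preprocessed [kgml_pathway()].
#' @param store A `resource_store`.
#' @return A tibble with one row per reaction: `reaction_id`, `status`,
#'   `n_diff_elements`, `report` (the full `balance_report` object).
#' @export
balance_reactions <- function(doc, store) {
  reps <- lapply(doc$reactions, reaction_atom_diff, store = store)
  tibble::tibble(
    reaction_id = vapply(reps, function(r) r$reaction_id, ""),
    status = vapply(reps, function(r) r$status, ""),
    n_diff_elements = vapply(reps, function(r) length(r$diff), integer(1)),
    report = reps)
}
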