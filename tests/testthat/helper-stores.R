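# Tiny real-chemistry store: ATP hydrolysis, used as an independent
# hand-counted oracle for the atom balance (both sides C10 H18 N5 O14 P3).
atp_store <- function() {
  resource_store(
    reactions = list(
      "rn:R00086" = reaction_record(
        id = "rn:R00086",
        equation = "cpd:C00002 + cpd:C00001 <=> cpd:C00008 + cpd:C00009",
        reversible = TRUE, ec_numbers = "3.6.1.3",
        definition = "ATP + H2O <=> ADP + Orthophosphate")),
    compounds = list(
      "cpd:C00002" = compound_record("cpd:C00002", names = "ATP",
                                     formula = "C10H16N5O13P3"),
      "cpd:C00001" = compound_record("cpd:C00001", names = "H2O",
                                     formula = "H2O"),
      "cpd:C00008" = compound_record("cpd:C00008", names = "ADP",
                                     formula = "C10H15N5O10P2"),
      "cpd:C00009" = compound_record("cpd:C00009",
                                     names = "Orthophosphate",
                                     formula = "H3PO4")))
}

# a reaction object wired by kegg id only (entry ids irrelevant for balance)
balance_rx <- function(id, sub_ids, prod_ids, sub_st = NULL, prod_st = NULL,
                       rtype = "irreversible") {
  mk <- function(ids, st) {
    if (is.null(st)) st <- rep(1, length(ids))
    Map(function(i, k) kgml_participant(entry_id = NA_integer_, kegg_id = i,
                                        stoichiometry = k), ids, st)
  }
  kgml_reaction(ids = id, rtype = rtype, substrates = mk(sub_ids, sub_st),
                products = mk(prod_ids, prod_st))
}

# find the reaction object carrying a given kegg reaction id
find_reaction <- function(doc, rid) {
  for (rx in doc$reactions) if (rid %in% rx$ids) return(rx)
  NULL
}

# all reaction ids of a document, as a sorted multiset
reaction_id_multiset <- function(doc)
  sort(unlist(lapply(doc$reactions, function(rx) rx$ids)))
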