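---
title: "Compiling KEGG pathways into SBML and BioPAX models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Compiling KEGG pathways into SBML and BioPAX models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kgmlconv)
```

## Why KGML cannot be translated one-to-one

KGML, the XML dialect in which KEGG distributes its pathway maps, is drawn
for human eyes. Entries (nodes) are duplicated wherever the layout needs a
second copy; several biochemical reactions are bundled into a single XML
reaction object; reaction participants and catalyzing enzymes are omitted
when the drawing does not need them; stoichiometric coefficients are absent
altogether; orthologous gene products that are not confirmed in the
organism are merely painted white; glycan identifiers stand in for compound
identifiers; and relations of subtype `compound` re-draw information that
the reaction list already carries. A model built by naive element-by-element
translation inherits every one of these shortcuts.

`kgmlconv` compiles KGML into systems-biology models in three stages:

1. **Correction** (`preprocess_pathway()`): prune pathway-reference and
   white entries (optionally orphans), split bundled reactions, complete
   every reaction against its database equation, canonicalize
   glycan/drug identifiers, merge graphical duplicates, and drop
   reaction-shadowing compound-relations.
2. **Verification** (`balance_reactions()`): a stoichiometry-weighted
   per-element atom count of both sides of every completed reaction.
3. **Serialization** (`translate_sbml()`, `translate_biopax()`): SBML
   L2V4 or L3V1 (with the qualitative-models and groups packages) and
   BioPAX Level 2 or 3, with SBO/GO/MI vocabulary terms, MIRIAM URN
   cross-references and human-readable notes on every element.

All knowledge that live KEGG sub-databases would supply — reaction
equations with reversibility and EC numbers, compound formulas and weights,
gene records with cross-references, identifier synonym tables — comes from
an offline **resource store** (`load_store()`), a directory of KEGG
flat-file style records. This keeps the converter deterministic and
network-free; a dump of real KEGG records can be ingested through the same
format.

## The correction pipeline and its assumptions

**Pruning.** Map-reference entries are not physical species and are removed
by default (keep them with `remove_pathway_refs = FALSE` if cross-pathway
links matter). A *white node* is removed only when its background is
`#FFFFFF` (case-insensitive) **and** its type is gene, ortholog or enzyme:
whiteness marks unconfirmed orthologous gene products, while compounds are
routinely drawn with white fill and must never be pruned by color. Orphan
removal is off by default — entries outside every relation and reaction are
a modeling preference, not an error. One refinement: a group entry that
carries components is never treated as an orphan even if nothing references
the group itself, because a complex is connected to the pathway through its
members. Removal order is pathway references, white nodes, then orphans,
with orphan status re-evaluated after the first two.

**Unbundling.** A reaction object holding *k* KEGG reaction identifiers
becomes *k* objects, each initially copying the participant lists; the
document-wide multiset of reaction identifiers is conserved (a tested
invariant).

**Completion.** For each reaction the store record supplies the truth:
reversibility is copied onto the object; each equation participant is
matched against the existing references by alias-closed identifier
comparison; unmatched participants are appended (creating a compound entry
when none exists, preferring an entry already wired to the reaction, else
the lowest entry id — both logged); stoichiometry is copied from the parsed
equation. Symbolic coefficients such as `n` or `n+1` are evaluated at
*n* = 1 for the numeric slot and carried verbatim, and they force the atom
balance to *indeterminate*. Enzymes are wired via EC numbers: every entry
whose gene record shares an EC number with the reaction record joins the
modifier set. Completion **never deletes** a participant that is absent
from the equation — it is logged as surplus — and it never invents gene
entries for unmatched EC numbers (they are logged), so no knowledge is
created out of nothing.

**Merging.** Graphical copies (same type, same sorted identifier list)
collapse onto the lowest-id representative; relations, participants, group
components and modifier sets are rewritten through the merge map, so a
protein drawn twice, each copy catalyzing a different reaction, ends up
catalyzing both. Graphics are dropped from merged representatives — the
models here are layout-free. Merging runs last in the pipeline because the
earlier steps want to see the original copies; the individual operations
are exported, so other orderings can be composed by hand.

## Atom balance

Each compound formula is parsed into exact integer element counts. The
formula dialect covers element symbols with counts, one level of
parenthesized groups with a multiplier, polymeric repeat units
(`(C6H10O5)n`, counted once and flagged), a generic substituent `R`
(flagged), and trailing charge tokens, which are stripped from counting and
noted in the report (protons are not balanced). Deeper nesting is a formula
error. Every quantity in play — coefficients and element counts — is an
integer, so plain integer arithmetic in doubles is exact and the reports
are reproducible byte for byte.

A reaction is *balanced* iff every substrate-minus-product element
difference is zero and nothing is flagged; *indeterminate* when any
participant is generic, polymeric, symbolically weighted or missing a
formula; otherwise *unbalanced*, with the per-element difference reported.
Imbalances are **never auto-corrected**: a missing `H` could equally be a
missing water, phosphate or larger cofactor pair, so the finding is
attached as a comment on the exported reaction (SBML notes, BioPAX
comments) for a human to resolve.

## Serialization choices

**SBML.** Species types are fixed by SBO terms from the material-entity
branch: compound 247, enzyme/gene/ortholog 252, group 253, map 552. Entries
of type `reaction` form no species in core; under the qual package they do
get a qualitative species (transitions must be able to target them).
Irreversible reactions mark substrates SBO 15 and products SBO 11;
reversible reactions mark all participants with the generic-reactant term
SBO 10 — a document never mixes the two schemes inside one reaction.
Relations cannot be expressed in core SBML; with the L3 qual package each
relation becomes one transition carrying the subtype's SBO term (the most
specific modification subtype wins when several are present; the rest
become extra CV terms) and its GO term where the vocabulary grid lists one.
No function terms, maximum levels or initial levels are emitted — KEGG
carries no qualitative logic to fill them with. Groups become `groups`
package objects on L3 (kind *partonomy*), otherwise complex species with
SBO 253 and a `HAS_PART` CV term. Everything lives in a single default
compartment, because KEGG encodes no compartmentalization. No initial
amounts or concentrations are written (unknown); species are
non-boundary, non-constant.

**BioPAX.** Entry types map to SmallMolecule / Protein / Complex / Pathway;
reactions to BiochemicalReaction with per-participant stoichiometry
(explicit `Stoichiometry` objects on L3, `physicalEntityParticipant`
coefficients on L2) plus a Catalysis whose Controller is the enzyme set and
whose Controlled is the reaction. Relation subtypes follow the published
grid: modification-family relations synthesize a target-state variant
entity (deterministic suffix, e.g. `_p` for phosphorylation) and wrap the
conversion in a Control whose controller is the source entity; downstream
relations always reference the unmodified base entity, since KGML cannot
say in which form a protein participates. Expression/repression become
TemplateReaction + TemplateReactionRegulation on L3 and fall back to
Conversion + Control on L2; binding/dissociation becomes a ComplexAssembly
only when the assembled (or disassembled) end is a complex, else a generic
Conversion; missing interaction pools both entities in a
MolecularInteraction (physicalInteraction on L2). Every translated relation
carries an InteractionVocabulary with its SBO (always) and MI/GO terms
(where listed). The vocabulary grid publishes no MOD accessions, so L3
ModificationFeatures carry a human-readable SequenceModificationVocabulary
term only. Relations that point at reaction-type entries are wired
interaction-to-interaction, which BioPAX allows naturally. One open reading
is flagged: for a plain activation no controller distinct from the source
exists, so the source entity is used as the Controller of the synthesized
conversion.

**Annotations.** Cross-references are MIRIAM URNs
(`urn:miriam:<collection>:<id>`), chosen over identifiers.org URLs for L2
compatibility. Single-identity entries get `IS` terms; multi-gene nodes get
`HAS_VERSION` per member (a node standing for alternative gene products is
not identical to any single one); groups get `HAS_PART` over their members'
identifiers. CAS numbers, when present in a record, appear in notes only —
no vocabulary qualifier is asserted for them. Identifier sanitization for
SBML replaces non-word characters with underscores, prefixes identifiers
that start with a digit, and suffixes numeric counters on collisions, so
ids are valid and injective; all element ordering is deterministic, making
serialization byte-reproducible — a property the test suite asserts.

## What the synthetic fixtures emulate

`generate_fixture(seed, fixture_config())` builds a matched
pathway/store pair in a reserved synthetic namespace (`cpd:CT####`,
`rn:RT####`, `syn:1####`, ...), with every defect class the pipeline
corrects, each planted in a distinct reaction so defects never interact:
bundled reaction objects, omitted participants, duplicated entries, white
ortholog nodes, map links, orphans, groups, reaction-type entries, one
relation per vocabulary subtype, reaction-shadowing compound-relations,
glycan-aliased participants, enzymes left unwired from their reaction, and
optionally atom imbalances. Store equations are balanced *by construction*
— each product's formula is the exact stoichiometry-weighted element sum of
its substrates' — and a planted imbalance perturbs a product formula by a
known delta whose expected per-element difference is recorded in the
manifest by an independent count at build time. The defaults (five
reactions, one defect per class, the full 14-subtype relation vocabulary)
keep a fixture at a few dozen entries, so the property suites run hundreds
of fixtures in seconds; those sizes are stated here as the package's test
conditions.

What the generator does **not** emulate: real KEGG identifier semantics
(ids are synthetic), organism-scale pathway sizes, records with missing or
malformed formulas beyond the planted cases, multi-compartment artwork, and
the long tail of historical KGML dialect quirks. Green tests therefore
demonstrate the correctness of the correction/translation logic under
controlled conditions, not coverage of every irregularity in two decades of
KEGG exports; the round-trip and validation layers are designed to surface
such irregularities as explicit findings rather than silent drops.

## Degenerate inputs and numerical corner cases

An empty pathway serializes to a valid document (empty lists, lone pathway
object). Reactions absent from the store are left untouched and logged as
errors rather than guessed at. Missing formulas degrade the balance to
indeterminate with the participant listed. Alias resolution is closed at
store-load time and rejects cycles. Group members removed by pruning
shrink the member list with a warning. Stoichiometry `1` is left implicit
in the KGML dialect extension so raw and round-tripped documents stay
byte-compatible.

## Limitations

No rate laws, kinetics or flux constraints are generated; no SBML layout
or SBGN output; no live KEGG access (by design); BioPAX pathway-step
ordering and evidence objects are not emitted; charge and isotope balance
are out of scope for the atom check. The structural self-validations
(unique ids, resolvable references, mandatory vocabulary presence,
controller/controlled pairing) are internal checks, not replacements for
the official SBML/BioPAX validator services.
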