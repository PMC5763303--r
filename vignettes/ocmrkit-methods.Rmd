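---
title: "ocmrkit: methods, design decisions and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ocmrkit: methods, design decisions and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ocmrkit)
```

## Scope and model

`ocmrkit` models the knowledge surrounding anti-rheumatism traditional
Chinese drugs (TCDs) as three layers:

1. **Ontology slices** (`ontology_graph`): rooted, possibly multi-parent
   is-a DAGs with term labels, synonyms and non-hierarchical cross-links
   (notably `has_role`, the relation ChEBI uses to attach application
   roles such as *anti-inflammatory agent* to chemical classes). Multiple
   inheritance is first-class: every closure is computed over the DAG, not
   a spanning tree, because chemical ontologies routinely classify one
   compound under several parents.
2. **A curation table** (`curation_table`): one annotated fact per line —
   a drug's source organism/anatomic part, a chemical ingredient (with an
   optional ChEBI CURIE and curator-assigned roles), or an adverse event
   (with an optional OAE CURIE). A line's `drug` field may list several
   drugs separated by `;`, mirroring how printed ingredient tables list
   one chemical with its drug set; such a line counts as **one**
   ingredient entry but expands to one (drug, chemical) pair per drug when
   the knowledge graph is built.
3. **A knowledge graph** (`knowledge_graph`): deduplicated
   subject–predicate–object triples over CURIEs. Drug classes are minted
   deterministically (`OCMR:0000001`, ... in sorted-label order) and
   placed under their drug-category class; everything else is an
   existential restriction `Drug ⊑ ∃R.Filler` in the OWL view and a direct
   edge in the materialized view.

### Identifier and label conventions

Ontology identifiers occur in two dialects — `CHEBI:9747` (OBO files) and
`CHEBI_9747` (PURL IRIs and some printed tables). Both normalize to the
colon CURIE, the canonical internal form; conversion to and from OBO PURL
IRIs is lossless. Labels are matched case-insensitively with whitespace
collapsed, and a trailing "TCD" token on drug labels is ignored, because
curated sources are inconsistent in exactly these ways. Printed label
*variants* that differ in more than case/whitespace (e.g. a typo in a
drug name) are deliberately **not** merged: silently unifying them would
hide a curation problem, so they surface as distinct drugs, while two
labels that collapse under normalization are rejected as a duplicate.

## Subset extraction with computed intermediates

Extraction re-implements the MIREOT-style "import a minimal slice"
operation:

- `minimal_common_ancestors(g, ts)` returns the minimal elements of the
  common ancestor-or-self set of `ts`. Under multiple inheritance there
  can be several (a diamond yields both shoulders); for a singleton it is
  the term itself; for terms with no common root it is the empty set (a
  forest is valid input, not an error).
- `lca_closure(g, seeds)` is the least fixpoint of adding the minimal
  common ancestors of every **pair** of current members. The pairwise
  fixpoint — rather than the single LCA of the whole seed set — is a
  deliberate choice: it retains *every* branch point between seeds, which
  is what extraction tools display (tiger/snake keep their own branch
  point below the all-seed ancestor). On trees this equals the classical
  Steiner-node set (internal nodes with at least two seed-bearing child
  subtrees), which the test suite uses as an independent oracle.
- `extract_subset()` then keeps, per mode, the closure
  (`computed_intermediates`), all ancestors (`all_intermediates`) or the
  seeds only (`no_intermediates`), optionally plus reachable roots, and
  re-wires each kept node to its **nearest kept ancestors**: `a` becomes a
  parent of `c` iff some original is-a path from `c` to `a` contains no
  other kept node. This rule can create several parents (faithful DAG
  semantics) and provably preserves `is_ancestor(x, y)` for all seed
  pairs, a property the tests assert against a path-enumeration oracle on
  random DAGs.

Whether terms strictly between a seed and its nearest computed
intermediate should ever be retained is not well defined by the
extraction tools this mimics; the three modes above are this package's
explicit contract, and no further mode is offered.

## Knowledge-graph construction and serialization

Relations are configuration, not constants. Defaults: `has_part`
(BFO:0000051) for drug→chemical, `participates_in` (RO:0000056) for
drug→AE, `has_role` (RO:0000087) for chemical→role. No standard relation
exists for drug→source-organism and drug→anatomic-part in this domain, so
`produced_by` (RO:0003001) and `derives_from` (RO:0001000) are defaults
that a user can override via `relation_config()`.

Curator-assigned roles (the table's role sections) and ontology-asserted
roles (ChEBI `has_role` cross-links) feed the *same* `has_role` triples.
This is what lets the packaged ingredient-table fixture reproduce the
published role counts without a full ChEBI release, while an imported
slice adds subsumption-derived roles on top.

Two serializations are written from one graph:

- **Turtle** preserves the OWL semantics — existential triples appear as
  the `rdfs:subClassOf [ a owl:Restriction ; owl:onProperty R ;
  owl:someValuesFrom O ]` pattern — with subjects sorted by IRI, so output
  is byte-stable.
- **N-Triples** is the materialized, query-ready view: restrictions are
  flattened to direct predicate edges (plus `rdfs:label` literals), which
  is what the query engine and CLI consume. Both readers accept exactly
  the dialect the writers emit; they are not general RDF parsers (no
  general-purpose RDF library is assumed to be installed).

## Query semantics

`match_pattern()` implements conjunctive basic graph patterns only — no
OPTIONAL, FILTER or property paths — because that is the entire
expressiveness the role queries need. A pattern's predicate may carry a
`transitive` flag meaning "match through the **reflexive**-transitive
closure of `rdfs:subClassOf`"; reflexivity is required so that
`(?r, subClassOf*, role)` admits the role term itself. Role subsumption is
therefore a two-pattern join rather than an engine built-in. Results are
deduplicated and sorted by bound CURIEs; an all-constant query acts as an
ASK (zero-column result with one row when the pattern holds); unknown
constants yield empty results, not errors.

`chemicals_with_role()` applies subsumption on both sides: chemical `C`
bears role `R` iff some ancestor-or-self of `C` carries `has_role` to `R`
or to a descendant of `R`. The candidate universe defaults to the objects
of `has_part` triples — i.e. actual drug ingredients — so role assertions
on intermediate chemical classes count only through the ingredients below
them. Dual-role membership is reported two ways (`dual_role_chemicals()`):
*section-wise* (entries whose own role set contains both roles, matching a
printed table's dual-role section, 9 on the packaged fixture) and
*set-wise* (chemicals whose entries jointly cover both roles, 11 on the
packaged fixture). The two disagree on the fixture because the printed
table itself lists two chemicals once per single-role section; the
discrepancy is reported, never silently resolved.

## Adverse-event analyses

AE sharing is computed on normalized labels by default, not on OAE
CURIEs, because curated AE lists typically contain entries that lack
ontology ids at curation time; CURIE-level grouping is available via
`ae_profile(ct, by = "curie")`. Whether a published "total AE" count means
table rows or (drug, AE) pairs is often ambiguous, so the profile reports
both (`total_ae_rows`, `total_drug_ae_pairs`) alongside `unique_aes`.
Top-level classification assigns an AE to **every** designated class among
its ancestors-or-self — OAE is a DAG and no tie-break rule is defensible,
so multi-membership is the contract.

## The synthetic generator: what a green test establishes

`generate_dag()` builds a layered random DAG (each term draws 1 to
`max_parents` parents uniformly from earlier terms), which is acyclic *by
construction* — no post-hoc cycle repair — and guarantees every term
reaches a root. `generate_curation()` plants, with a single integer seed
driving one PRNG stream:

- one source fact per drug (26 drugs by default, matching the size of the
  curated drug set the package targets);
- 2–8 leaf chemicals per drug by default (real curated drugs carry up to
  ~125 ChEBI-mapped chemicals each, but the structural properties under
  test — dedup, per-drug tallies, role recovery — do not depend on that
  scale, so the default is kept small for test speed);
- `has_role` links attached at depth 2, so role recovery genuinely
  exercises subsumption through intermediate classes;
- AEs on 6 of the drugs realizing the sharing spec exactly. The default
  spec is the published sharing structure — 3 AEs in 5 drugs, 10 in 4,
  7 in 3 — extended by `(2, 20), (1, 144)` so unique AEs total 184; the
  published analysis does not state the k=1/k=2 split, so this long-tail
  split was chosen once as realistic (most AEs are drug-specific) and is
  not tuned.

The generator's truth ledger (`role_leaves`, `drug_chemicals`,
`ae_histogram`) is computed from construction-time data structures, not by
calling the package's closures, so end-to-end recovery tests are a real
cross-check. What the generator does **not** emulate: realistic chemical
nomenclature, correlated role/branch structure, AE severity or frequency,
curation noise such as conflicting CURIEs. A green recovery test
establishes that the pipeline's set algebra is exact on clean structured
input, not that it is robust to dirty curation.

## Numerical and degenerate-input choices

There are no floating-point tolerances anywhere: every computed quantity
is a finite set or count, and all equality in tests is exact. Determinism
is achieved by sorted iteration (CURIEs sorted with radix order, i.e.
byte order independent of locale) rather than by seeding; only the
generators consume randomness. Degenerate inputs are defined rather than
rejected wherever a sensible value exists: empty tables parse to zero
rows; a singleton seed set is its own minimal common ancestor; disjoint
forests have an empty common-ancestor set; an unknown role yields an
empty set with a warning (an unknown *term* in a graph operation is an
error, since it indicates a broken CURIE, not an empty answer). Obsolete
terms are loaded but excluded from all closures, mirroring OBO practice
without losing provenance.

## Known limitations

- The OBO parser covers the flat-file subset the package writes
  (`[Term]`, `id`, `name`, `synonym`, `is_a`, `relationship`,
  `is_obsolete`); it is not an OBO 1.4 or OWL functional-syntax parser,
  and there is no reasoner — subsumption is graph reachability, not EL
  classification.
- Absolute branch counts (e.g. how many ingredients are diterpenoids)
  depend on the ontology release supplied; the packaged ChEBI slice is a
  small hand-built stand-in for worked examples, not a release snapshot.
- The role-term CURIEs used by default (`CHEBI:67079`, `CHEBI:35610`) are
  configuration; results do not depend on the particular ids, only on the
  table/slice using the same ones.
- Organism CURIEs in the packaged ingredient-table fixture are synthetic
  placeholders (the supplementary file with real taxon ids is not
  redistributable); they exist only to satisfy the source-fact invariant.
- Instance-level (ABox) modeling, annotation properties beyond labels,
  and any network access (fetching ontologies, SPARQL endpoints) are out
  of scope.
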