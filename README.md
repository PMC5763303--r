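# ocmrkit

Tools for ontology-based representation and analysis of anti-rheumatism
traditional Chinese drugs (TCDs).

## The problem

Traditional Chinese decoction-piece drugs used against rheumatism are
complex: each drug is made from an anatomic part of a plant or animal and
contains dozens to hundreds of chemical ingredients, some with known
biological roles (anti-inflammatory agent, antineoplastic agent) and some
with reported adverse events (AEs). Curated knowledge about these drugs is
scattered across an annotation table and several reference ontologies —
ChEBI for chemicals and their roles, NCBITaxon for source organisms, PO and
UBERON for anatomic parts, OAE for adverse events, TCMDPO for the drug
classification itself.

`ocmrkit` turns such a curated table plus ontology slices into an
integrated knowledge graph and runs the analyses this field relies on:

- **Ontology model** — an in-memory, multi-parent is-a DAG for OBO-flavoured
  slices, with `ancestors()` / `descendants()` closures and `has_role`
  cross-links.
- **MIREOT-style subset extraction** — `extract_subset()` keeps a seed set
  plus its *computed intermediates*: for seed terms `S`, the kept set is the
  least fixpoint of adding all minimal common ancestors
  `mca(x, y), x, y ∈ S` (all branch points, not just the single LCA), and
  kept nodes are re-wired to their nearest kept ancestors so that
  `is_ancestor(x, y)` is preserved for every seed pair.
- **Curation ingest** — a long-format TSV, one annotated fact per line
  (source organism/anatomy, chemical ingredient with ChEBI CURIE and curator
  roles, or AE), validated with per-drug and global tallies.
- **Knowledge-graph building** — drug classes are minted deterministically
  and linked by existential axioms `Drug ⊑ ∃ has_part . Chemical`,
  `Drug ⊑ ∃ participates_in . AE`, `Chemical ⊑ ∃ has_role . Role`,
  serialized as Turtle (OWL restriction pattern) and materialized N-Triples.
- **Query engine** — conjunctive triple patterns with variables and an
  is-a-transitivity flag, the basic-graph-pattern fragment of SPARQL;
  role subsumption is the join
  `(?x, has_role, ?r) ∧ (?r, subClassOf*, role)`.
- **Role / branch / AE analyses** — `chemicals_with_role()` applies
  subsumption on both the chemical and the role side; `branch_members()`
  answers "which ingredients are diterpenoids?"; `ae_profile()` and
  `sharing_histogram()` quantify how AEs are shared across drugs and
  `top_level_ae_classes()` groups them by body system.
- **Synthetic data** — seeded generators (`generate_dag()`,
  `generate_curation()`) emit ontology slices and curation tables with a
  ground-truth ledger, so the whole pipeline is testable end to end without
  any download.

## Worked example

The package ships a transcription of the published ingredient table
(42 chemical entries over 19 drug labels, with curator role sections) at
`inst/extdata/table1_curation.tsv`:

```r
library(ocmrkit)
ct <- parse_curation_table(system.file("extdata", "table1_curation.tsv",
                                       package = "ocmrkit"))
validate_curation(ct)
#> validation_report: 19 drugs, 42 chemical entries (40 unique CURIEs), 0 AE rows (0 unique labels)
#> warnings:
#>   - ...

kg <- build_kg(ct)
kg
#> knowledge_graph: 166 triples (19 is_a, 147 existential), 93 terms (27 unlabeled)

role_report(kg, c("anti-inflammatory" = "CHEBI:67079",
                  "antineoplastic"    = "CHEBI:35610"))
#> role_report:
#>   anti-inflammatory: 18 chemicals
#>   antineoplastic: 33 chemicals
#>   anti-inflammatory & antineoplastic: 11 shared

dual <- dual_role_chemicals(ct)
lengths(dual)
#> section_wise     set_wise
#>            9           11
```

18 chemicals bear the anti-inflammatory role and 33 the antineoplastic
role, matching the published analysis. The table's own dual-role section
lists 9 chemicals, while the set-wise intersection over all its entries is
11 (maslinic acid and triptonide each also appear in one single-role
section); `ocmrkit` reports both readings rather than resolving the
discrepancy. The same 33 antineoplastic chemicals are returned by the
query engine:

```r
nrow(match_pattern(kg, list(
  triple_pattern("?x", "RO:0000087", "?r"),
  triple_pattern("?r", "rdfs:subClassOf", "CHEBI:35610", transitive = TRUE))))
#> [1] 33
```

Computed-intermediates extraction on the packaged toy taxonomy (the three
animal drug sources):

```r
g <- load_obo(system.file("extdata", "toy_taxonomy.obo", package = "ocmrkit"))
res <- extract_subset(g, c("TOYTAX:0000005", "TOYTAX:0000006", "TOYTAX:0000007"),
                      extraction_options("computed_intermediates",
                                         include_roots = TRUE))
res
#> subset_result: 3 seeds, 3 computed intermediates, 6 terms total
term_label(res$graph, res$computed_terms)
#> [1] "Eukaryota" "Bilateria" "Amniota"
```

Bilateria is inserted as the closest common ancestor of tiger, snake and
silkworm (and Amniota as the tiger/snake branch point), exactly the
"includeComputedIntermediates" behaviour of ontology extraction tools.

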