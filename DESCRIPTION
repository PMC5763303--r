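Package: ocmrkit
Title: Ontology-Based Representation and Analysis of Anti-Rheumatism
    Traditional Chinese Drugs
Version: 0.1.0
Authors@R:
    person("OCMR", "Toolkit Developers", email = "ocmrkit@example.org",
           role = c("aut", "cre"))
Description: Tools for building and analysing a multi-ontology knowledge
    graph of traditional Chinese decoction-piece drugs (TCDs) used against
    rheumatism. Provides an in-memory DAG model for OBO-flavoured ontology
    slices (ChEBI, NCBITaxon, PO, UBERON, OAE, TCMDPO), MIREOT-style subset
    extraction with computed intermediate ancestors, ingest and validation
    of a curated drug annotation table, template-driven generation of
    existential OWL axioms serialized as Turtle and N-Triples, a conjunctive
    triple-pattern query engine with is-a subsumption, role-based chemical
    classification and structural branch analyses, adverse-event sharing
    analyses, and seeded synthetic-data generators with ground-truth
    ledgers for end-to-end testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
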