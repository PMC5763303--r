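# fixtures built in code, shared across test files

toy_taxonomy_path <- function() {
  system.file("extdata", "toy_taxonomy.obo", package = "ocmrkit")
}
table1_path <- function() {
  system.file("extdata", "table1_curation.tsv", package = "ocmrkit")
}
lipids_path <- function() {
  system.file("extdata", "toy_chebi_lipids.obo", package = "ocmrkit")
}

TIGER <- "TOYTAX:0000005"
SNAKE <- "TOYTAX:0000006"
SILKWORM <- "TOYTAX:0000007"
AMNIOTA <- "TOYTAX:0000003"
INSECTA <- "TOYTAX:0000004"
BILATERIA <- "TOYTAX:0000002"
EUKARYOTA <- "TOYTAX:0000001"

AI_ROLE <- "CHEBI:67079"   # anti-inflammatory agent
AN_ROLE <- "CHEBI:35610"   # antineoplastic agent

# diamond: x,y both under a and b; a,b under r
diamond_graph <- function() {
  terms <- data.frame(id = c("D:1", "D:2", "D:3", "D:4", "D:5"),
                      label = c("r", "a", "b", "x", "y"),
                      stringsAsFactors = FALSE)
  edges <- data.frame(child = c("D:2", "D:3", "D:4", "D:4", "D:5", "D:5"),
                      parent = c("D:1", "D:1", "D:2", "D:3", "D:2", "D:3"),
                      stringsAsFactors = FALSE)
  ontology_graph(terms, edges)
}

# one-fact minimal curation table
mini_table <- function(extra = NULL) {
  base <- data.frame(
    drug = c("Drug A", "Drug A"),
    category = c("cat 1", ""),
    fact_type = c("source", "chemical"),
    organism_id = c("TAX:1", ""),
    anatomy_id = "",
    chemical_label = c("", "triptolide"),
    chemical_id = c("", "CHEBI:9747"),
    roles = c("", "anti-inflammatory"),
    ae_label = "", ae_id = "",
    stringsAsFactors = FALSE)
  curation_table(rbind(base, extra))
}

write_tmp_obo <- function(lines) {
  path <- withr_tempfile(".obo")
  writeLines(c("format-version: 1.2", "", lines), path)
  path
}

# tempfile registered for cleanup without importing withr
withr_tempfile <- function(ext) tempfile(fileext = ext)
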