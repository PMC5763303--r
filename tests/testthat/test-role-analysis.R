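fixture_kg <- function(with_chebi = FALSE) {
  ct <- parse_curation_table(table1_path())
  onts <- if (with_chebi) list(chebi = load_obo(lipids_path())) else list()
  build_kg(ct, onts)
}

test_that("curator-asserted roles reproduce the published counts", {
  kg <- fixture_kg()
  ai <- chemicals_with_role(kg, AI_ROLE)
  an <- chemicals_with_role(kg, AN_ROLE)
  expect_equal(length(ai), 18)
  expect_equal(length(an), 33)
  ov <- role_overlap(kg, AI_ROLE, AN_ROLE)
  expect_equal(length(ov$both), 11)              # set-wise over the table
  expect_setequal(c(ov$only_r1, ov$both), ai)
  # the printed dual-role section itself lists 9
  dual <- dual_role_chemicals(parse_curation_table(table1_path()))
  expect_equal(length(dual$section_wise), 9)
  expect_equal(length(dual$set_wise), 11)
  expect_true(all(dual$section_wise %in% dual$set_wise))
})

test_that("role subsumption propagates through an imported hierarchy", {
  # triptolide's anti-inflammatory role is asserted in the ChEBI slice on
  # the chemical itself; a role planted on an ancestor must reach leaves
  terms <- data.frame(
    id = c("C:1", "C:2", "C:3", "R:1", "R:2"),
    label = c("parent chemical", "leaf a", "leaf b", "role", "subrole"),
    stringsAsFactors = FALSE)
  edges <- data.frame(child = c("C:2", "C:3", "R:2"),
                      parent = c("C:1", "C:1", "R:1"),
                      stringsAsFactors = FALSE)
  cross <- data.frame(subject = "C:1", relation = "RO:0000087",
                      object = "R:2", stringsAsFactors = FALSE)
  g <- ontology_graph(terms, edges, cross)
  rows <- data.frame(
    drug = c("D", "D", "D"), category = "",
    fact_type = c("source", "chemical", "chemical"),
    organism_id = c("TAX:1", "", ""), anatomy_id = "",
    chemical_label = c("", "leaf a", "leaf b"),
    chemical_id = c("", "C:2", "C:3"), roles = "", ae_label = "", ae_id = "",
    stringsAsFactors = FALSE)
  kg <- build_kg(curation_table(rows), list(toy = g))
  # role asserted on the ancestor C:1 with the subrole: both leaves bear
  # the subrole and, by role-side subsumption, the parent role too
  expect_equal(chemicals_with_role(kg, "R:2"), c("C:2", "C:3"))
  expect_equal(chemicals_with_role(kg, "R:1"), c("C:2", "C:3"))
  # monotonicity in the role hierarchy
  expect_true(all(chemicals_with_role(kg, "R:2") %in%
                  chemicals_with_role(kg, "R:1")))
  expect_warning(out <- chemicals_with_role(kg, "R:999"), "not present")
  expect_equal(out, character())
})

test_that("chemicals_with_role equals the brute-force oracle on random KGs", {
  for (seed in 1:6) {
    kg <- random_kg(seed + 40, n_nodes = 12, n_triples = 45)
    roles <- unique(kg$triples$object[kg$triples$predicate == "RO:0000087"])
    for (role in utils::head(roles, 3)) {
      expect_equal(chemicals_with_role(kg, role),
                   oracle_chemicals_with_role(kg, role),
                   label = sprintf("seed %d role %s", seed, role))
    }
  }
})

test_that("branch membership is a descendant query", {
  g <- load_obo(lipids_path())
  chems <- c("CHEBI:9740", "CHEBI:9747", "CHEBI:63959")
  expect_equal(branch_members(g, "CHEBI:23849", chems),       # diterpenoid
               c("CHEBI:9740", "CHEBI:9747"))
  expect_equal(branch_members(g, "CHEBI:36615", chems),       # triterpenoid
               "CHEBI:63959")
  expect_equal(branch_members(g, "CHEBI:25872", chems),       # pentacyclic
               "CHEBI:63959")
  # nested branches: pentacyclic triterpenoids are triterpenoids
  expect_true(all(branch_members(g, "CHEBI:25872", chems) %in%
                  branch_members(g, "CHEBI:36615", chems)))
  expect_equal(branch_members(g, "CHEBI:50906", chems), character())
  expect_error(branch_members(g, "CHEBI:424242", chems), "unknown")
})

test_that("role and branch reports assemble the sets", {
  kg <- fixture_kg()
  rep <- role_report(kg, c("anti-inflammatory" = AI_ROLE,
                           "antineoplastic" = AN_ROLE))
  expect_equal(lengths(rep$roles),
               c("anti-inflammatory" = 18L, "antineoplastic" = 33L))
  expect_equal(length(rep$pairwise[["anti-inflammatory & antineoplastic"]]), 11)
  drug_ids <- mint_drug_terms(parse_curation_table(table1_path())$drugs)
  ctr <- rep$per_drug[[drug_ids[["Common Threewingnut Root"]]]]
  expect_true("CHEBI:9747" %in% ctr$`anti-inflammatory`)

  br <- branch_report(load_obo(lipids_path()),
                      c(diterpenoid = "CHEBI:23849",
                        triterpenoid = "CHEBI:36615"),
                      c("CHEBI:9740", "CHEBI:9747", "CHEBI:63959"))
  expect_equal(unname(br$sizes), c(2L, 1L))

  empty <- knowledge_graph(NULL)
  expect_warning(rep0 <- role_report(empty, AN_ROLE))
  expect_equal(lengths(rep0$roles), c("CHEBI:35610" = 0L))
})
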