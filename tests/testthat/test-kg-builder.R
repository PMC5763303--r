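test_that("drug ids are minted deterministically in sorted-label order", {
  ids <- mint_drug_terms(c("b drug", "a drug", "b drug"))
  expect_equal(ids, c("a drug" = "OCMR:0000001", "b drug" = "OCMR:0000002"))
  ct <- parse_curation_table(table1_path())
  m1 <- mint_drug_terms(ct$drugs)
  m2 <- mint_drug_terms(parse_curation_table(table1_path())$drugs)
  expect_identical(m1, m2)                      # idempotent across parses
  expect_equal(length(unique(m1)), 19)          # injective on the 19 drugs
  expect_error(mint_drug_terms("x", namespace = "bad prefix"), "namespace")
})

test_that("apply_template stamps one existential triple per qualifying row", {
  ct <- mini_table()
  res <- apply_template(axiom_template("{drug} has_part {chemical_id}"), ct)
  expect_equal(nrow(res$triples), 1)
  expect_equal(res$triples$predicate, "BFO:0000051")
  expect_equal(res$triples$object, "CHEBI:9747")
  expect_equal(res$skipped, 1)   # the source row

  # no AE rows: everything is skipped
  tab <- parse_curation_table(table1_path())
  rows <- tab$rows[tab$rows$fact_type == "chemical", ]
  rows$roles <- vapply(rows$roles, paste, character(1), collapse = ";")
  rows$drugs <- NULL
  chem_only <- curation_table(rows)
  res2 <- apply_template(axiom_template("{drug} participates_in {ae_id}"),
                         chem_only)
  expect_equal(nrow(res2$triples), 0)
  expect_equal(res2$skipped, 42)

  expect_error(apply_template(axiom_template("{drug} part_of {chemical_id}"),
                              ct), "unknown relation")
  expect_error(axiom_template("{drug} has_part {nonsense}"), "not a table column")
})

test_that("build_kg realizes the design pattern on the fixture", {
  ct <- parse_curation_table(table1_path())
  kg <- build_kg(ct)
  rc <- relation_config()
  hp <- kg$triples[kg$triples$predicate == rc$has_part$curie, ]
  # 60 (drug, chemical) pairs in the table, 58 distinct
  expect_equal(nrow(hp), 58)
  # the worked axiom: Common Threewingnut Root 'has part' some triptolide
  drug_ids <- mint_drug_terms(ct$drugs)
  ctr <- drug_ids[["Common Threewingnut Root"]]
  expect_true(any(hp$subject == ctr & hp$object == "CHEBI:9747"))
  # drugs are classified under their category
  isa <- kg$triples[kg$triples$axiom_kind == "is_a", ]
  expect_equal(nrow(isa), 19)
  expect_equal(kg$labels[["CHEBI:9747"]], "triptolide")
  # duplicate normalized drug labels are rejected
  bad <- ct$rows
  # "Mulberry Twig TCD" collapses onto "Mulberry Twig" under normalization
  bad$drug[bad$drug == "Mulberry Ttwig"] <- "Mulberry  Twig TCD"
  bad$roles <- vapply(bad$roles, paste, character(1), collapse = ";")
  bad$drugs <- NULL
  expect_error(suppressWarnings(build_kg(curation_table(bad))), "duplicate drug label")
})

test_that("triple count decomposes exactly on synthetic tables", {
  for (seed in 1:5) {
    p <- generator_params(n_drugs = 6, n_terms = 30, n_ae_drugs = 4,
                          ae_sharing_spec = list(c(3, 2), c(1, 4)),
                          seed = seed)
    dag <- generate_dag(p)
    gen <- generate_curation(p, dag$graph, dag$truth)
    ct <- gen$table
    kg <- build_kg(ct, list(syn = dag$graph))
    imported <- nrow(dag$graph$is_a) + nrow(dag$graph$cross_links)
    ex_rows <- sum(vapply(seq_len(nrow(ct$rows)), function(i) {
      r <- ct$rows[i, ]
      length(r$drugs[[1]]) * ((nzchar(r$chemical_id)) + (nzchar(r$ae_id)) +
        (nzchar(r$organism_id)) + (nzchar(r$anatomy_id))) +
        length(r$roles[[1]])
    }, numeric(1)))
    # every synthetic drug has exactly one category => n_drugs minted is_a
    expect_equal(nrow(kg$triples), imported + ex_rows + p$n_drugs)
  }
})

test_that("Turtle and N-Triples exports are stable and round-trip", {
  ct <- mini_table()
  kg <- build_kg(ct, list(chebi = load_obo(lipids_path())))
  ttl1 <- tempfile(fileext = ".ttl")
  ttl2 <- tempfile(fileext = ".ttl")
  export_turtle(kg, ttl1)
  export_turtle(build_kg(ct, list(chebi = load_obo(lipids_path()))), ttl2)
  expect_identical(readLines(ttl1), readLines(ttl2))
  kg_ttl <- read_turtle(ttl1)
  expect_equal(kg_ttl$triples, kg$triples)
  expect_equal(kg_ttl$labels[names(kg$labels)], kg$labels)

  nt <- tempfile(fileext = ".nt")
  export_ntriples(kg, nt)
  kg_nt <- read_ntriples(nt)
  expect_equal(kg_nt$triples[, c("subject", "predicate", "object")],
               kg$triples[, c("subject", "predicate", "object")])
})

test_that("empty and single-triple graphs serialize as expected", {
  empty <- knowledge_graph(NULL)
  ttl <- tempfile(fileext = ".ttl")
  export_turtle(empty, ttl)
  lines <- readLines(ttl)
  expect_true(all(grepl("^@prefix|^$", lines)))

  one <- knowledge_graph(data.frame(subject = "OCMR:0000001",
                                    predicate = "BFO:0000051",
                                    object = "CHEBI:9747",
                                    axiom_kind = "existential"))
  export_turtle(one, ttl)
  expect_equal(sum(grepl("owl:Restriction", readLines(ttl))), 1)
  nt <- tempfile(fileext = ".nt")
  export_ntriples(one, nt)
  expect_equal(length(readLines(nt)), 1)
})
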