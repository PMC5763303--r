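ae_table <- function(rows) {
  drugs <- unique(unlist(lapply(rows, `[[`, 1)))
  src <- do.call(rbind, lapply(seq_along(drugs), function(i) {
    data.frame(drug = drugs[[i]], category = "", fact_type = "source",
               organism_id = paste0("TAX:", i), anatomy_id = "",
               chemical_label = "", chemical_id = "", roles = "",
               ae_label = "", ae_id = "", stringsAsFactors = FALSE)
  }))
  ae <- do.call(rbind, lapply(rows, function(r) {
    data.frame(drug = r[[1]], category = "", fact_type = "ae",
               organism_id = "", anatomy_id = "", chemical_label = "",
               chemical_id = "", roles = "", ae_label = r[[2]],
               ae_id = if (length(r) > 2) r[[3]] else "",
               stringsAsFactors = FALSE)
  }))
  curation_table(rbind(src, ae))
}

test_that("AE labels group under normalization and count once per drug", {
  ct <- ae_table(list(list("A", "Nausea "), list("B", "nausea"),
                      list("B", "NAUSEA"), list("B", "rash")))
  p <- ae_profile(ct)
  expect_equal(p$unique_aes, 2)
  expect_equal(p$aes[["nausea"]], c("A", "B"))
  expect_equal(p$total_ae_rows, 4)
  expect_equal(p$total_drug_ae_pairs, 3)   # B's duplicate nausea collapses
  # no AE rows at all
  p0 <- ae_profile(mini_table())
  expect_equal(p0$unique_aes, 0)
  expect_equal(p0$total_ae_rows, 0)
})

test_that("profiles are invariant under row order and case permutations", {
  rows <- list(list("A", "Dizziness"), list("B", "dizziness"),
               list("B", "Anorexia"), list("C", "anorexia"),
               list("A", "rash"))
  p1 <- ae_profile(ae_table(rows))
  p2 <- ae_profile(ae_table(rev(rows)))
  expect_equal(p1$aes, p2$aes)
})

test_that("sharing histogram partitions the unique AEs", {
  ct <- ae_table(list(list("A", "x"), list("B", "x"), list("C", "x"),
                      list("A", "y"), list("B", "y"), list("A", "z")))
  p <- ae_profile(ct)
  h <- sharing_histogram(p)
  expect_equal(names(h), c("1", "2", "3"))
  expect_equal(lengths(h), c("1" = 1L, "2" = 1L, "3" = 1L))
  expect_equal(sum(lengths(h)), p$unique_aes)
  expect_setequal(unlist(h), names(p$aes))
  expect_equal(aes_shared_by_at_least(p, 2), c("x", "y"))
  expect_equal(aes_shared_by_at_least(p, 1), c("x", "y", "z"))
  expect_error(aes_shared_by_at_least(p, 0), "k must be")
})

test_that("histogram partition identity holds on generated tables", {
  for (seed in 1:6) {
    p <- generator_params(n_drugs = 8, n_terms = 25, n_ae_drugs = 5,
                          ae_sharing_spec = list(c(4, 2), c(3, 3), c(1, 5)),
                          seed = seed)
    dag <- generate_dag(p)
    ct <- generate_curation(p, dag$graph)$table
    prof <- ae_profile(ct)
    h <- sharing_histogram(prof)
    expect_equal(sum(lengths(h)), prof$unique_aes)
    expect_setequal(unlist(h, use.names = FALSE), names(prof$aes))
  }
})

test_that("AEs classify into designated top-level classes, multi-membership allowed", {
  # toy AE ontology: 7 sensory + 1 other neuro AE under behavioral and
  # neurological; 3 digestive; 2 skin; one AE under two designated classes
  terms <- data.frame(
    id = c("OAE:1", "OAE:10", "OAE:11", "OAE:20", "OAE:30",
           paste0("OAE:10", 1:7), "OAE:108",
           paste0("OAE:20", 1:3), paste0("OAE:30", 1:2), "OAE:400"),
    label = c("adverse event", "behavioral and neurological AE",
              "sensory capability AE", "digestive system AE", "skin AE",
              paste("sensory AE", 1:7), "other neuro AE",
              paste("digestive AE", 1:3), paste("skin AE", 1:2),
              "mixed AE"),
    stringsAsFactors = FALSE)
  edges <- data.frame(
    child = c("OAE:10", "OAE:11", "OAE:20", "OAE:30",
              paste0("OAE:10", 1:7), "OAE:108",
              paste0("OAE:20", 1:3), paste0("OAE:30", 1:2),
              "OAE:400", "OAE:400"),
    parent = c("OAE:1", "OAE:10", "OAE:1", "OAE:1",
               rep("OAE:11", 7), "OAE:10",
               rep("OAE:20", 3), rep("OAE:30", 2),
               "OAE:20", "OAE:30"),
    stringsAsFactors = FALSE)
  g <- ontology_graph(terms, edges)
  aes <- c(paste0("OAE:10", 1:8), paste0("OAE:20", 1:3), paste0("OAE:30", 1:2))
  res <- top_level_ae_classes(g, aes, c("OAE:10", "OAE:20", "OAE:30"))
  expect_equal(lengths(res$classes),
               c("OAE:10" = 8L, "OAE:20" = 3L, "OAE:30" = 2L))
  expect_equal(res$unclassified, character())
  # an AE under two designated branches appears in both groups
  res2 <- top_level_ae_classes(g, c(aes, "OAE:400"),
                               c("OAE:20", "OAE:30"))
  expect_true("OAE:400" %in% res2$classes[["OAE:20"]])
  expect_true("OAE:400" %in% res2$classes[["OAE:30"]])
  expect_setequal(res2$unclassified, paste0("OAE:10", 1:8))
  # designated = root assigns every AE
  res3 <- top_level_ae_classes(g, aes, "OAE:1")
  expect_equal(lengths(res3$classes), c("OAE:1" = 13L))
  expect_error(top_level_ae_classes(g, aes, "OAE:999"), "unknown")
})
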