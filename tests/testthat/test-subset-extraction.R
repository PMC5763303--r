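test_that("minimal_common_ancestors on hand-checked cases", {
  g <- load_obo(toy_taxonomy_path())
  expect_equal(minimal_common_ancestors(g, c(TIGER, SNAKE, SILKWORM)),
               BILATERIA)
  expect_equal(minimal_common_ancestors(g, TIGER), TIGER)
  expect_equal(minimal_common_ancestors(g, c(TIGER, SNAKE)), AMNIOTA)

  d <- diamond_graph()
  expect_equal(minimal_common_ancestors(d, c("D:4", "D:5")),
               c("D:2", "D:3"))                    # multiple inheritance
  expect_equal(minimal_common_ancestors(d, c("D:4", "D:5")),
               oracle_mca(d, c("D:4", "D:5")))
  expect_error(minimal_common_ancestors(g, "TOYTAX:9999999"), "unknown")
})

test_that("disjoint forest roots give an empty MCA set, not an error", {
  terms <- data.frame(id = c("F:1", "F:2"), label = c("a", "b"),
                      stringsAsFactors = FALSE)
  g <- ontology_graph(terms)
  expect_equal(minimal_common_ancestors(g, c("F:1", "F:2")), character())
  expect_equal(lca_closure(g, c("F:1", "F:2")), c("F:1", "F:2"))
})

test_that("lca_closure adds exactly the branch points", {
  g <- load_obo(toy_taxonomy_path())
  cl <- lca_closure(g, c(TIGER, SNAKE, SILKWORM))
  expect_setequal(cl, c(TIGER, SNAKE, SILKWORM, AMNIOTA, BILATERIA))
  # chain: seeds on one root-to-leaf path stay unchanged
  expect_equal(lca_closure(g, c(EUKARYOTA, BILATERIA, TIGER)),
               sort(c(EUKARYOTA, BILATERIA, TIGER)))
  # idempotence
  expect_equal(lca_closure(g, cl), cl)
})

test_that("lca_closure equals the Steiner-node oracle on random trees", {
  for (seed in 1:20) {
    tr <- random_tree(8L + seed %% 20, seed)
    set.seed(seed + 1000)
    seeds <- sample(tr$ids, min(length(tr$ids), 2L + seed %% 4))
    expect_equal(lca_closure(tr$graph, seeds),
                 oracle_steiner_closure(tr$parents, sort(unique(seeds))))
  }
})

test_that("lca_closure is monotone on trees", {
  for (seed in 1:8) {
    tr <- random_tree(15, seed)
    set.seed(seed)
    small <- sample(tr$ids, 3)
    big <- union(small, sample(tr$ids, 3))
    expect_true(all(lca_closure(tr$graph, small) %in%
                    lca_closure(tr$graph, big)))
  }
})

test_that("extract_subset reproduces the worked taxonomy example", {
  g <- load_obo(toy_taxonomy_path())
  res <- extract_subset(g, c(TIGER, SNAKE, SILKWORM),
                        extraction_options("computed_intermediates",
                                           include_roots = TRUE))
  expect_setequal(term_ids(res$graph),
                  c(TIGER, SNAKE, SILKWORM, AMNIOTA, BILATERIA, EUKARYOTA))
  expect_setequal(res$computed_terms, c(AMNIOTA, BILATERIA, EUKARYOTA))
  got <- res$graph$is_a
  want <- data.frame(
    child = c(TIGER, SNAKE, AMNIOTA, SILKWORM, BILATERIA),
    parent = c(AMNIOTA, AMNIOTA, BILATERIA, BILATERIA, EUKARYOTA),
    stringsAsFactors = FALSE)
  ord <- function(e) e[order(e$child, e$parent), ]
  expect_equal(ord(got), ord(want), ignore_attr = TRUE)
})

test_that("extracting every term reproduces the original graph", {
  g <- load_obo(toy_taxonomy_path())
  res <- extract_subset(g, term_ids(g), extraction_options("no_intermediates"))
  expect_setequal(term_ids(res$graph), term_ids(g))
  ord <- function(e) e[order(e$child, e$parent), ]
  expect_equal(ord(res$graph$is_a), ord(g$is_a), ignore_attr = TRUE)
})

test_that("extraction modes nest and preserve seed reachability", {
  for (seed in 1:10) {
    p <- generator_params(n_terms = 10L + (seed %% 4) * 10L, max_parents = 3,
                          seed = seed + 100)
    g <- generate_dag(p)$graph
    ids <- grep("^SYN:", term_ids(g), value = TRUE)
    set.seed(seed)
    seeds <- sample(ids, min(length(ids), 5))
    res_c <- extract_subset(g, seeds, extraction_options("computed_intermediates"))
    res_a <- extract_subset(g, seeds, extraction_options("all_intermediates"))
    res_n <- extract_subset(g, seeds, extraction_options("no_intermediates"))
    expect_gte(nrow(res_c$graph$terms), length(unique(seeds)))
    expect_lte(nrow(res_c$graph$terms), nrow(res_a$graph$terms))
    expect_equal(nrow(res_n$graph$terms), length(unique(seeds)))
    for (mode_res in list(res_c, res_a, res_n)) {
      for (x in seeds) for (y in seeds) {
        if (x == y) next
        expect_equal(is_ancestor(mode_res$graph, x, y),
                     oracle_reachable(g, x, y),
                     label = sprintf("seed %d: %s ancestor of %s", seed, x, y))
      }
    }
  }
})

test_that("computed-intermediates extraction equals Steiner contraction on trees", {
  for (seed in 1:10) {
    tr <- random_tree(12L + seed, seed + 55)
    set.seed(seed)
    seeds <- sample(tr$ids, 4)
    res <- extract_subset(tr$graph, seeds,
                          extraction_options("computed_intermediates"))
    expect_setequal(term_ids(res$graph),
                    oracle_steiner_closure(tr$parents, sort(unique(seeds))))
  }
})

test_that("cross-links are carried only when requested and only between kept terms", {
  g <- load_obo(lipids_path())
  seeds <- c("CHEBI:9747", "CHEBI:67079")
  res0 <- extract_subset(g, seeds, extraction_options("no_intermediates"))
  expect_equal(nrow(res0$graph$cross_links), 0)
  res1 <- extract_subset(g, seeds, extraction_options("no_intermediates",
                                                      carry_cross_links = TRUE))
  expect_equal(res1$graph$cross_links$subject, "CHEBI:9747")
  expect_equal(res1$graph$cross_links$object, "CHEBI:67079")
})
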