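# independent brute-force oracles; these deliberately use exhaustive path
# enumeration / nested loops, not the package's BFS closures

# all terms lying on any upward is-a path from t (exhaustive recursion)
oracle_ancestors <- function(g, t) {
  obsolete <- g$terms$id[g$terms$obsolete]
  rec <- function(v) {
    ps <- setdiff(g$parents[[v]], obsolete)
    if (length(ps) == 0) return(character())
    unique(c(ps, unlist(lapply(ps, rec), use.names = FALSE)))
  }
  sort(unique(rec(t)))
}

oracle_reachable <- function(g, a, b) a %in% oracle_ancestors(g, b)

# minimal elements of the common ancestor-or-self set, by enumeration
oracle_mca <- function(g, ts) {
  common <- Reduce(intersect,
                   lapply(ts, function(t) c(t, oracle_ancestors(g, t))))
  if (length(common) == 0) return(character())
  keep <- vapply(common, function(a) {
    !any(vapply(setdiff(common, a),
                function(b) a %in% oracle_ancestors(g, b), logical(1)))
  }, logical(1))
  sort(common[keep])
}

# Steiner nodes of a TREE: seeds plus internal nodes with >= 2 children
# whose subtrees contain a seed
oracle_steiner_closure <- function(tree_parents, seeds) {
  nodes <- names(tree_parents)
  children <- lapply(nodes, function(v) {
    nodes[vapply(tree_parents, function(p) length(p) == 1 && p == v,
                 logical(1))]
  })
  names(children) <- nodes
  subtree_has_seed <- function(v) {
    v %in% seeds || any(vapply(children[[v]], subtree_has_seed, logical(1)))
  }
  steiner <- nodes[vapply(nodes, function(v) {
    sum(vapply(children[[v]], subtree_has_seed, logical(1))) >= 2
  }, logical(1))]
  sort(union(seeds, steiner))
}

# reflexive reachability over subClassOf triples, by path enumeration
oracle_kg_reach <- function(triples, x, y) {
  if (x == y) return(TRUE)
  isa <- triples[triples$predicate == "rdfs:subClassOf", , drop = FALSE]
  rec <- function(v, seen) {
    ps <- setdiff(isa$object[isa$subject == v], seen)
    if (y %in% ps) return(TRUE)
    any(vapply(ps, function(p) rec(p, c(seen, p)), logical(1)))
  }
  rec(x, x)
}

# nested-loop join over triple patterns (same pattern semantics as
# match_pattern, computed by exhaustive backtracking)
oracle_match <- function(kg, patterns) {
  triples <- kg$triples
  nodes <- unique(c(triples$subject, triples$object))
  closure_rows <- function() {
    out <- list()
    for (x in nodes) for (y in nodes) {
      if (oracle_kg_reach(triples, x, y)) {
        out[[length(out) + 1L]] <- c(x, y)
      }
    }
    out
  }
  pat_rows <- lapply(patterns, function(p) {
    if (p$transitive) {
      lapply(closure_rows(), function(r) c(subject = r[[1]],
                                           predicate = p$predicate,
                                           object = r[[2]]))
    } else {
      lapply(seq_len(nrow(triples)), function(i) {
        c(subject = triples$subject[[i]], predicate = triples$predicate[[i]],
          object = triples$object[[i]])
      })
    }
  })
  is_var <- function(x) startsWith(x, "?")
  sols <- list()
  rec <- function(k, binding) {
    if (k > length(patterns)) {
      sols[[length(sols) + 1L]] <<- binding
      return()
    }
    p <- patterns[[k]]
    for (row in pat_rows[[k]]) {
      b <- binding
      ok <- TRUE
      for (part in c("subject", "predicate", "object")) {
        v <- p[[part]]
        if (is_var(v)) {
          nm <- sub("^\\?", "", v)
          if (!is.null(b[[nm]]) && b[[nm]] != row[[part]]) { ok <- FALSE; break }
          b[[nm]] <- row[[part]]
        } else if (v != row[[part]]) { ok <- FALSE; break }
      }
      if (ok) rec(k + 1L, b)
    }
  }
  rec(1L, list())
  if (length(sols) == 0) return(NULL)
  df <- unique(do.call(rbind, lapply(sols, function(b) {
    as.data.frame(b[order(names(b))], stringsAsFactors = FALSE)
  })))
  df <- df[do.call(order, unname(as.list(df))), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# brute-force role bearers: all (ingredient, role) pairs by reachability
oracle_chemicals_with_role <- function(kg, role, rc = relation_config()) {
  tr <- kg$triples
  chems <- unique(tr$object[tr$predicate == rc$has_part$curie])
  hr <- tr[tr$predicate == rc$has_role$curie, , drop = FALSE]
  hit <- vapply(chems, function(ch) {
    any(vapply(seq_len(nrow(hr)), function(i) {
      oracle_kg_reach(tr, ch, hr$subject[[i]]) &&
        oracle_kg_reach(tr, hr$object[[i]], role)
    }, logical(1)))
  }, logical(1))
  sort(chems[hit])
}

# small random tree over ids T:1..n (node 1 is the root)
random_tree <- function(n, seed) {
  set.seed(seed)
  ids <- paste0("T:", seq_len(n))
  parent <- c(NA, vapply(2:n, function(i) sample.int(i - 1L, 1L), integer(1)))
  edges <- data.frame(child = ids[-1], parent = ids[parent[-1]],
                      stringsAsFactors = FALSE)
  g <- ontology_graph(data.frame(id = ids, label = ids,
                                 stringsAsFactors = FALSE), edges)
  parents_list <- lapply(seq_len(n), function(i) {
    if (is.na(parent[[i]])) character() else ids[parent[[i]]]
  })
  names(parents_list) <- ids
  list(graph = g, parents = parents_list, ids = ids)
}

# random materialized KG: acyclic subClassOf backbone + random other edges
random_kg <- function(seed, n_nodes = 12, n_triples = 40) {
  set.seed(seed)
  nodes <- paste0("N:", seq_len(n_nodes))
  preds <- c("rdfs:subClassOf", "RO:0000087", "BFO:0000051")
  rows <- lapply(seq_len(n_triples), function(i) {
    p <- sample(preds, 1L)
    if (p == "rdfs:subClassOf") {
      ij <- sort(sample.int(n_nodes, 2L))   # child index > parent index
      data.frame(subject = nodes[ij[[2]]], predicate = p,
                 object = nodes[ij[[1]]], stringsAsFactors = FALSE)
    } else {
      ij <- sample.int(n_nodes, 2L)
      data.frame(subject = nodes[ij[[1]]], predicate = p,
                 object = nodes[ij[[2]]], stringsAsFactors = FALSE)
    }
  })
  knowledge_graph(do.call(rbind, rows))
}
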