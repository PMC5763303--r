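#' Extraction options for ontology subsetting
#'
#' @param mode one of `"computed_intermediates"` (keep seeds plus every
#'   minimal common ancestor, the Ontofox-style
#'   "includeComputedIntermediates" behaviour), `"all_intermediates"`
#'   (keep seeds plus all their ancestors) or `"no_intermediates"` (seeds
#'   only).
#' @param include_roots also keep the roots reachable from the kept set.
#' @param carry_cross_links restrict and carry over cross-links whose
#'   subject and object are both kept.
#' @return an `extraction_options` object.
#' @export
extraction_options <- function(mode = c("computed_intermediates",
                                        "all_intermediates",
                                        "no_intermediates"),
                               include_roots = FALSE,
                               carry_cross_links = FALSE) {
  mode <- match.arg(mode)
  structure(list(mode = mode, include_roots = isTRUE(include_roots),
                 carry_cross_links = isTRUE(carry_cross_links)),
            class = "extraction_options")
}

.anc_or_self <- function(g, t) c(t, ancestors(g, t))

#' Minimal common ancestors of a term set
#'
#' Returns every term `a` that is an ancestor-or-self of all of `ts` and
#' such that no descendant of `a` has that property (the minimal elements
#' of the common-ancestor set). Under multiple inheritance the result can
#' contain more than one term; for a singleton set it is the term itself;
#' for terms in disjoint components of a forest it is empty (not an
#' error).
#'
#' In the toy taxonomy fixture, `Bilateria` is the single closest common
#' ancestor of tiger, snake and silkworm.
#'
#' @param g an [ontology_graph].
#' @param ts character vector of term CURIEs (at least one), declared in
#'   `g`.
#' @return sorted character vector of CURIEs.
#' @export
minimal_common_ancestors <- function(g, ts) {
  ts <- unique(.check_terms(g, ts))
  stopifnot(length(ts) >= 1)
  common <- Reduce(intersect, lapply(ts, function(t) .anc_or_self(g, t)))
  if (length(common) == 0) return(character())
  # a is minimal iff no other common ancestor is a descendant of a
  minimal <- vapply(common, function(a) {
    !any(vapply(setdiff(common, a), function(b) is_ancestor(g, a, b),
                logical(1)))
  }, logical(1))
  sort(common[minimal])
}

#' Computed-intermediates closure of a seed set
#'
#' The least fixpoint of adding the minimal common ancestors of every
#' pair of current members until nothing changes. This is the set of
#' branch points ("computed intermediate" terms) a MIREOT-style extractor
#' inserts between seed terms: for tiger, snake and silkworm it adds
#' `Amniota` (tiger/snake) and `Bilateria` (all three). The closure is
#' idempotent, finite and independent of iteration order; members are
#' processed in sorted CURIE order so results are byte-stable.
#'
#' @param g an [ontology_graph].
#' @param seeds nonempty character vector of term CURIEs declared in `g`.
#' @return sorted character vector: the seeds plus all computed
#'   intermediates.
#' @export
lca_closure <- function(g, seeds) {
  cur <- sort(unique(.check_terms(g, seeds)))
  stopifnot(length(cur) >= 1)
  repeat {
    added <- character()
    n <- length(cur)
    if (n >= 2) {
      for (i in seq_len(n - 1L)) {
        for (j in seq(i + 1L, n)) {
          mca <- minimal_common_ancestors(g, c(cur[[i]], cur[[j]]))
          added <- c(added, setdiff(mca, cur))
        }
      }
    }
    added <- unique(added)
    if (length(added) == 0) break
    cur <- sort(c(cur, added))
  }
  cur
}

#' MIREOT-style subset extraction with computed intermediates
#'
#' Extracts a minimal sub-hierarchy around `seeds`. The kept node set is
#' determined by `opts$mode` (see [extraction_options()]); reachable roots
#' are added when `include_roots`. Edges in the result connect each kept
#' node to its nearest kept proper ancestors: child `c` gets parent `a`
#' iff some is-a path from `c` to `a` in `g` contains no other kept node.
#' This preserves seed-pair reachability exactly: for any seeds `x, y`,
#' `is_ancestor(x, y)` holds in the result iff it holds in `g`. Under
#' multiple inheritance the rule can produce several parents; that is
#' intended.
#'
#' @param g an [ontology_graph].
#' @param seeds character vector of seed term CURIEs declared in `g`.
#' @param opts an [extraction_options()] object.
#' @return a `subset_result`: list with `graph` (the extracted
#'   [ontology_graph]), `seed_terms` and `computed_terms` (intermediates
#'   added beyond the seeds).
#' @examples
#' g <- load_obo(system.file("extdata", "toy_taxonomy.obo", package = "ocmrkit"))
#' res <- extract_subset(g, c("TOYTAX:0000005", "TOYTAX:0000006", "TOYTAX:0000007"),
#'                       extraction_options("computed_intermediates", include_roots = TRUE))
#' sort(term_ids(res$graph))
#' @export
extract_subset <- function(g, seeds, opts = extraction_options()) {
  seeds <- sort(unique(.check_terms(g, seeds)))
  stopifnot(inherits(opts, "extraction_options"))
  kept <- switch(opts$mode,
    computed_intermediates = lca_closure(g, seeds),
    all_intermediates = sort(unique(c(seeds, unlist(lapply(seeds, ancestors,
                                                           g = g))))),
    no_intermediates = seeds)
  if (opts$include_roots) {
    reach_roots <- unique(unlist(lapply(seeds, function(s) {
      intersect(.anc_or_self(g, s), g$roots)
    })))
    kept <- sort(union(kept, reach_roots))
  }

  # nearest kept ancestor: BFS upward, stopping expansion at kept nodes
  obs <- .obsolete_ids(g)
  nearest_kept <- function(c0) {
    found <- character()
    seen <- character()
    frontier <- g$parents[[c0]]
    while (length(frontier) > 0) {
      frontier <- setdiff(unique(frontier), c(seen, obs))
      seen <- c(seen, frontier)
      hit <- intersect(frontier, kept)
      found <- c(found, hit)
      expand <- setdiff(frontier, kept)
      frontier <- unlist(g$parents[expand], use.names = FALSE)
    }
    sort(unique(found))
  }
  edges <- do.call(rbind, lapply(kept, function(c0) {
    ps <- nearest_kept(c0)
    if (length(ps) == 0) return(NULL)
    data.frame(child = c0, parent = ps, stringsAsFactors = FALSE)
  }))

  idx <- match(kept, g$terms$id)
  terms <- g$terms[idx, , drop = FALSE]
  rownames(terms) <- NULL
  cross <- NULL
  if (opts$carry_cross_links && nrow(g$cross_links) > 0) {
    keep <- g$cross_links$subject %in% kept & g$cross_links$object %in% kept
    cross <- g$cross_links[keep, , drop = FALSE]
  }
  structure(list(graph = ontology_graph(terms, edges, cross),
                 seed_terms = seeds,
                 computed_terms = setdiff(kept, seeds)),
            class = "subset_result")
}

#' @export
print.subset_result <- function(x, ...) {
  cat(sprintf("subset_result: %d seeds, %d computed intermediates, %d terms total\n",
              length(x$seed_terms), length(x$computed_terms),
              nrow(x$graph$terms)))
  invisible(x)
}
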