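#' Construct an in-memory ontology graph
#'
#' An `ontology_graph` is the in-memory form of an ontology slice (ChEBI,
#' NCBITaxon, PO, UBERON, OAE, TCMDPO, ...): a rooted, possibly
#' multi-parent is-a DAG of terms with labels, plus non-hierarchical
#' cross-links such as ChEBI's `has_role`. Multi-parent is-a is allowed
#' (ChEBI requires it), so all closures are over the DAG, not a tree.
#'
#' Validation enforces: all edge endpoints declared, no directed is-a
#' cycle, no duplicate term ids. Obsolete terms are kept (provenance) but
#' excluded from closures. Cross-links never participate in the cycle
#' check.
#'
#' @param terms data.frame with columns `id` (CURIE), `label`, and
#'   optionally `obsolete` (logical) and `synonyms` (list column).
#' @param is_a data.frame with columns `child`, `parent` (CURIEs), or NULL.
#' @param cross_links data.frame with columns `subject`, `relation`,
#'   `object` (CURIEs), or NULL.
#' @return an object of class `ontology_graph` with elements `terms`,
#'   `is_a`, `cross_links`, `parents`/`children` adjacency lists and the
#'   computed `roots` (non-obsolete terms with no parent).
#' @export
ontology_graph <- function(terms, is_a = NULL, cross_links = NULL) {
  stopifnot(is.data.frame(terms), all(c("id", "label") %in% names(terms)))
  terms$id <- curie_normalize(as.character(terms$id))
  terms$label <- as.character(terms$label)
  if (is.null(terms$obsolete)) terms$obsolete <- FALSE
  if (is.null(terms$synonyms)) terms$synonyms <- replicate(nrow(terms), character(), simplify = FALSE)
  if (anyDuplicated(terms$id)) {
    stop("duplicate term id(s): ",
         paste(unique(terms$id[duplicated(terms$id)]), collapse = ", "))
  }
  empty_edges <- data.frame(child = character(), parent = character(),
                            stringsAsFactors = FALSE)
  if (is.null(is_a) || nrow(is_a) == 0) {
    is_a <- empty_edges
  } else {
    is_a <- data.frame(child = curie_normalize(as.character(is_a$child)),
                       parent = curie_normalize(as.character(is_a$parent)),
                       stringsAsFactors = FALSE)
    is_a <- unique(is_a)
  }
  if (is.null(cross_links) || nrow(cross_links) == 0) {
    cross_links <- data.frame(subject = character(), relation = character(),
                              object = character(), stringsAsFactors = FALSE)
  } else {
    cross_links <- unique(data.frame(
      subject = curie_normalize(as.character(cross_links$subject)),
      relation = curie_normalize(as.character(cross_links$relation)),
      object = curie_normalize(as.character(cross_links$object)),
      stringsAsFactors = FALSE))
  }

  ids <- terms$id
  ends <- unique(c(is_a$child, is_a$parent, cross_links$subject,
                   cross_links$object))
  missing <- setdiff(ends, ids)
  if (length(missing) > 0) {
    stop("dangling edge endpoint(s) not declared as terms: ",
         paste(sort(missing), collapse = ", "))
  }

  cyc <- .find_cycle(ids, is_a)
  if (!is.null(cyc)) {
    stop("is_a cycle detected involving: ", paste(sort(cyc), collapse = ", "))
  }

  parents <- split(is_a$parent, factor(is_a$child, levels = ids))
  children <- split(is_a$child, factor(is_a$parent, levels = ids))
  live <- ids[!terms$obsolete]
  has_parent <- vapply(parents[live], length, integer(1)) > 0
  g <- list(terms = terms, is_a = is_a, cross_links = cross_links,
            parents = parents, children = children,
            roots = sort(live[!has_parent]))
  class(g) <- "ontology_graph"
  g
}

# Kahn topological sort; returns NULL if acyclic, else the residual
# (cyclic) node set.
.find_cycle <- function(ids, is_a) {
  if (nrow(is_a) == 0) return(NULL)
  indeg <- table(factor(is_a$parent, levels = ids))
  out_adj <- split(is_a$parent, factor(is_a$child, levels = ids))
  indeg <- as.integer(indeg)
  names(indeg) <- ids
  queue <- ids[indeg == 0]
  removed <- 0L
  while (length(queue) > 0) {
    v <- queue[[1]]
    queue <- queue[-1]
    removed <- removed + 1L
    for (p in out_adj[[v]]) {
      indeg[[p]] <- indeg[[p]] - 1L
      if (indeg[[p]] == 0L) queue <- c(queue, p)
    }
  }
  if (removed == length(ids)) return(NULL)
  names(indeg)[indeg > 0]
}

#' @export
print.ontology_graph <- function(x, ...) {
  cat(sprintf("ontology_graph: %d terms (%d obsolete), %d is_a edges, %d cross-links, %d roots\n",
              nrow(x$terms), sum(x$terms$obsolete), nrow(x$is_a),
              nrow(x$cross_links), length(x$roots)))
  invisible(x)
}

#' @export
format.ontology_graph <- function(x, ...) {
  sprintf("<ontology_graph: %d terms, %d edges>", nrow(x$terms), nrow(x$is_a))
}

#' Query terms of an ontology graph
#'
#' @param g an [ontology_graph].
#' @param t a term CURIE (either dialect).
#' @return `term_ids()` returns all term CURIEs; `has_term()` a logical;
#'   `term_label()` the label of `t`.
#' @export
term_ids <- function(g) {
  stopifnot(inherits(g, "ontology_graph"))
  g$terms$id
}

#' @rdname term_ids
#' @export
has_term <- function(g, t) {
  curie_normalize(t) %in% g$terms$id
}

#' @rdname term_ids
#' @export
term_label <- function(g, t) {
  t <- .check_terms(g, t)
  g$terms$label[match(t, g$terms$id)]
}

.check_terms <- function(g, ts) {
  stopifnot(inherits(g, "ontology_graph"))
  ts <- curie_normalize(ts)
  unknown <- setdiff(ts, g$terms$id)
  if (length(unknown) > 0) {
    stop("unknown term(s): ", paste(unknown, collapse = ", "))
  }
  ts
}

.obsolete_ids <- function(g) g$terms$id[g$terms$obsolete]

# BFS over an adjacency list, excluding obsolete terms from the closure.
.closure <- function(g, t, adj) {
  skip <- .obsolete_ids(g)
  seen <- character()
  frontier <- setdiff(adj[[t]], skip)
  while (length(frontier) > 0) {
    seen <- union(seen, frontier)
    nxt <- unique(unlist(adj[frontier], use.names = FALSE))
    frontier <- setdiff(nxt, c(seen, skip))
  }
  sort(seen)
}

#' Transitive closure over is-a
#'
#' `ancestors()` returns the reflexive-free transitive is-a closure of a
#' term (all strictly more general terms); `descendants()` its inverse
#' (the term's whole branch, e.g. every chemical under `diterpenoid`);
#' `is_ancestor(g, a, b)` tests `a %in% ancestors(g, b)` and is
#' irreflexive. Obsolete terms never appear in closures.
#'
#' @param g an [ontology_graph].
#' @param t,a,b term CURIEs declared in `g` (either id dialect).
#' @return a sorted character vector of CURIEs (`ancestors`,
#'   `descendants`) or a single logical (`is_ancestor`).
#' @examples
#' g <- load_obo(system.file("extdata", "toy_taxonomy.obo", package = "ocmrkit"))
#' ancestors(g, "TOYTAX:0000005") # tiger -> Amniota, Bilateria, Eukaryota
#' @export
ancestors <- function(g, t) {
  t <- .check_terms(g, t)
  stopifnot(length(t) == 1L)
  .closure(g, t, g$parents)
}

#' @rdname ancestors
#' @export
descendants <- function(g, t) {
  t <- .check_terms(g, t)
  stopifnot(length(t) == 1L)
  .closure(g, t, g$children)
}

#' @rdname ancestors
#' @export
is_ancestor <- function(g, a, b) {
  a <- .check_terms(g, a)
  b <- .check_terms(g, b)
  a %in% ancestors(g, b)
}
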