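.kg_parents_map <- function(kg) {
  isa <- kg$triples[kg$triples$predicate == .IS_A, , drop = FALSE]
  split(isa$object, isa$subject)
}
.kg_children_map <- function(kg) {
  isa <- kg$triples[kg$triples$predicate == .IS_A, , drop = FALSE]
  split(isa$subject, isa$object)
}
.walk <- function(adj, start, or_self = TRUE) {
  seen <- character()
  frontier <- start
  while (length(frontier) > 0) {
    seen <- c(seen, frontier)
    frontier <- setdiff(unique(unlist(adj[frontier], use.names = FALSE)), seen)
  }
  if (or_self) seen else setdiff(seen, start)
}

# the chemical universe of a drug KG: everything asserted as an ingredient
.kg_ingredients <- function(kg, rc = relation_config()) {
  hp <- rc$has_part$curie
  sort(unique(kg$triples$object[kg$triples$predicate == hp]))
}

#' Chemicals bearing a role, with subsumption on both sides
#'
#' A chemical `C` (by default: any chemical asserted as a drug ingredient
#' via `has_part`) bears role `R` iff some ancestor-or-self of `C` in the
#' graph's is-a hierarchy carries a `has_role` link to `R` or to a
#' descendant of `R`. With no imported hierarchy this reduces to directly
#' asserted roles (the curator route); with a ChEBI slice imported,
#' role assertions on chemical classes propagate to the drug ingredients
#' below them.
#'
#' @param kg a [knowledge_graph].
#' @param role role term CURIE.
#' @param chemicals candidate chemical CURIEs; defaults to all `has_part`
#'   objects.
#' @param rc a [relation_config()] (for the `has_part`/`has_role` CURIEs).
#' @return sorted character vector of chemical CURIEs. An unknown role
#'   (no assertions anywhere in the graph) yields an empty set with a
#'   warning.
#' @export
chemicals_with_role <- function(kg, role, chemicals = NULL,
                                rc = relation_config()) {
  stopifnot(inherits(kg, "knowledge_graph"))
  role <- curie_normalize(role)
  if (is.null(chemicals)) chemicals <- .kg_ingredients(kg, rc)
  else chemicals <- curie_normalize(chemicals)
  hr <- kg$triples[kg$triples$predicate == rc$has_role$curie, , drop = FALSE]
  known <- role %in% c(kg$triples$subject, kg$triples$object)
  if (!known) {
    warning("role term not present in the knowledge graph: ", role)
    return(character())
  }
  role_set <- .walk(.kg_children_map(kg), role)      # role or descendant
  bearers <- unique(hr$subject[hr$object %in% role_set])
  if (length(bearers) == 0) return(character())
  parents <- .kg_parents_map(kg)
  hit <- vapply(chemicals, function(ch) {
    any(.walk(parents, ch) %in% bearers)
  }, logical(1))
  sort(chemicals[hit])
}

#' Overlap of two role-bearing chemical sets
#'
#' Partitions the union of the two sets into exclusive and shared members
#' (`both` is the set-wise intersection). Note that a printed table's own
#' "dual role" section can differ from the set-wise intersection; both
#' views can be computed, the section-wise one by restricting `chemicals`.
#'
#' @param kg a [knowledge_graph].
#' @param r1,r2 role term CURIEs.
#' @inheritParams chemicals_with_role
#' @return list with `only_r1`, `only_r2`, `both`.
#' @export
role_overlap <- function(kg, r1, r2, chemicals = NULL, rc = relation_config()) {
  s1 <- chemicals_with_role(kg, r1, chemicals, rc)
  s2 <- chemicals_with_role(kg, r2, chemicals, rc)
  list(only_r1 = setdiff(s1, s2), only_r2 = setdiff(s2, s1),
       both = intersect(s1, s2))
}

#' Chemicals falling in a structural branch of the ontology
#'
#' Branch membership is a descendant query: the members of, say, the
#' diterpenoid branch are the supplied chemicals lying at or below the
#' branch term in the is-a hierarchy.
#'
#' @param g an [ontology_graph] (e.g. a ChEBI slice).
#' @param branch branch term CURIE, declared in `g`.
#' @param chems character vector of chemical CURIEs (need not be declared).
#' @return sorted character vector: `chems` inside the branch.
#' @export
branch_members <- function(g, branch, chems) {
  branch <- .check_terms(g, branch)
  chems <- curie_normalize(chems)
  sort(intersect(chems, c(branch, descendants(g, branch))))
}

#' Role and branch reports
#'
#' `role_report()` assembles, for each role, the bearing chemicals, all
#' pairwise intersections, and a per-drug breakdown via the `has_part`
#' triples. `branch_report()` tabulates branch membership for a list of
#' branch terms. Both return JSON-serializable lists.
#'
#' @param kg a [knowledge_graph].
#' @param roles character vector of role CURIEs (names, if set, label the
#'   report entries).
#' @inheritParams chemicals_with_role
#' @return a `role_report`: list with `roles` (role -> chemicals),
#'   `pairwise` (role pair -> intersection), `per_drug` (drug ->
#'   role -> chemicals).
#' @export
role_report <- function(kg, roles, chemicals = NULL, rc = relation_config()) {
  roles_c <- curie_normalize(unname(unlist(roles)))
  nms <- if (is.null(names(roles))) roles_c else names(roles)
  sets <- lapply(roles_c, chemicals_with_role, kg = kg, chemicals = chemicals,
                 rc = rc)
  names(sets) <- nms
  pairwise <- list()
  if (length(sets) >= 2) {
    cmb <- utils::combn(seq_along(sets), 2)
    for (k in seq_len(ncol(cmb))) {
      i <- cmb[1, k]; j <- cmb[2, k]
      pairwise[[paste(nms[[i]], nms[[j]], sep = " & ")]] <-
        intersect(sets[[i]], sets[[j]])
    }
  }
  hp <- kg$triples[kg$triples$predicate == rc$has_part$curie, , drop = FALSE]
  per_drug <- lapply(split(hp$object, hp$subject), function(chems) {
    lapply(sets, intersect, x = unique(chems))
  })
  structure(list(roles = sets, pairwise = pairwise, per_drug = per_drug),
            class = "role_report")
}

#' @rdname role_report
#' @param g an [ontology_graph].
#' @param branches character vector of branch term CURIEs.
#' @param chems chemical CURIEs to classify.
#' @export
branch_report <- function(g, branches, chems) {
  branches_c <- curie_normalize(unname(unlist(branches)))
  nms <- if (is.null(names(branches))) branches_c else names(branches)
  sets <- lapply(branches_c, branch_members, g = g, chems = chems)
  names(sets) <- nms
  structure(list(branches = sets,
                 sizes = vapply(sets, length, integer(1))),
            class = "branch_report")
}

#' @export
print.role_report <- function(x, ...) {
  cat("role_report:\n")
  for (nm in names(x$roles)) {
    cat(sprintf("  %s: %d chemicals\n", nm, length(x$roles[[nm]])))
  }
  for (nm in names(x$pairwise)) {
    cat(sprintf("  %s: %d shared\n", nm, length(x$pairwise[[nm]])))
  }
  invisible(x)
}

#' @export
print.branch_report <- function(x, ...) {
  cat("branch_report:\n")
  for (nm in names(x$branches)) {
    cat(sprintf("  %s: %d members\n", nm, length(x$branches[[nm]])))
  }
  invisible(x)
}

#' Dual-role chemicals, section-wise and set-wise
#'
#' A printed ingredient table can disagree with itself: its "both roles"
#' section may omit chemicals that appear once in each single-role
#' section. This helper reports both readings from the curation table
#' alone: `section_wise` are chemicals some single entry of which carries
#' both roles (the table's own dual-role section), `set_wise` are
#' chemicals whose entries jointly cover both roles. `section_wise` is
#' always a subset of `set_wise`; a difference is reported, not resolved.
#'
#' @param ct a `curation_table`.
#' @param roles the two curator role names.
#' @return list with `section_wise` and `set_wise` (sorted chemical
#'   CURIEs; id-less entries are excluded).
#' @export
dual_role_chemicals <- function(ct, roles = c("anti-inflammatory",
                                              "antineoplastic")) {
  stopifnot(inherits(ct, "curation_table"), length(roles) == 2)
  rows <- ct$rows[ct$rows$fact_type == "chemical" & nzchar(ct$rows$chemical_id), ]
  section <- vapply(rows$roles, function(r) all(roles %in% r), logical(1))
  per_chem <- lapply(split(rows$roles, rows$chemical_id),
                     function(r) unique(unlist(r, use.names = FALSE)))
  setw <- names(per_chem)[vapply(per_chem, function(r) all(roles %in% r),
                                 logical(1))]
  list(section_wise = sort(unique(rows$chemical_id[section])),
       set_wise = sort(setw))
}
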