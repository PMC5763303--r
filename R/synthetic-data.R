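#' Parameters for the synthetic-data generators
#'
#' The defaults emulate the structure of a curated anti-rheumatism drug
#' table and its ontology slices: 26 drugs, a multi-parent chemical
#' hierarchy with role cross-links, and sparse adverse events confined to
#' 6 drugs whose sharing structure follows the published pattern — 3 AEs
#' shared by 5 drugs, 10 by 4, 7 by 3 (so 20 AEs are shared by at least
#' 3 drugs), and a long tail chosen so the unique AEs total 184.
#'
#' @param n_terms number of terms in the chemical hierarchy.
#' @param n_roots number of hierarchy roots.
#' @param max_parents maximum is-a parents per term (multi-parent DAG).
#' @param n_drugs number of drugs.
#' @param chemicals_per_drug integer range `c(lo, hi)` of ingredients
#'   sampled per drug.
#' @param n_role_terms number of role terms planted with `has_role`
#'   cross-links.
#' @param role_attachment_depth hierarchy depth at which roles attach.
#' @param n_ae_drugs number of drugs carrying adverse events.
#' @param ae_sharing_spec list of `c(k_drugs, n_aes)` pairs: plant
#'   `n_aes` adverse events each shared by exactly `k_drugs` drugs.
#' @param seed integer seed; one seed drives every random choice, so the
#'   emitted files are byte-identical across runs.
#' @return a `generator_params` object.
#' @export
generator_params <- function(n_terms = 60, n_roots = 1, max_parents = 2,
                             n_drugs = 26, chemicals_per_drug = c(2, 8),
                             n_role_terms = 2, role_attachment_depth = 2,
                             n_ae_drugs = 6,
                             ae_sharing_spec = list(c(5, 3), c(4, 10),
                                                    c(3, 7), c(2, 20),
                                                    c(1, 144)),
                             seed = 1L) {
  p <- list(n_terms = as.integer(n_terms), n_roots = as.integer(n_roots),
            max_parents = as.integer(max_parents),
            n_drugs = as.integer(n_drugs),
            chemicals_per_drug = as.integer(chemicals_per_drug),
            n_role_terms = as.integer(n_role_terms),
            role_attachment_depth = as.integer(role_attachment_depth),
            n_ae_drugs = as.integer(n_ae_drugs),
            ae_sharing_spec = lapply(ae_sharing_spec, as.integer),
            seed = as.integer(seed))
  counts <- c(p$n_terms, p$n_roots, p$max_parents, p$n_drugs,
              p$chemicals_per_drug, p$n_role_terms, p$n_ae_drugs)
  if (any(counts < 1)) stop("all generator counts must be positive")
  if (p$n_roots > p$n_terms) stop("infeasible params: n_roots > n_terms")
  if (p$n_ae_drugs > p$n_drugs) stop("infeasible params: n_ae_drugs > n_drugs")
  if (p$chemicals_per_drug[[1]] > p$chemicals_per_drug[[2]]) {
    stop("chemicals_per_drug range is reversed")
  }
  for (s in p$ae_sharing_spec) {
    if (length(s) != 2 || s[[1]] < 1 || s[[2]] < 0) {
      stop("ae_sharing_spec entries must be c(k_drugs, n_aes)")
    }
    if (s[[1]] > p$n_ae_drugs) {
      stop("infeasible ae_sharing_spec: k_drugs (", s[[1]],
           ") exceeds n_ae_drugs (", p$n_ae_drugs, ")")
    }
  }
  class(p) <- "generator_params"
  p
}

.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", globalenv())) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

.syn_id <- function(prefix, i) sprintf("%s:%07d", prefix, i)

#' Generate a random ontology DAG with planted role links
#'
#' Builds a layered random DAG: roots first, every later term draws 1 to
#' `max_parents` parents uniformly from the terms created before it, so
#' the graph is acyclic by construction and every term reaches a root. A
#' small role branch (`SYNROLE` terms under a role root) is appended and
#' each role term is attached by a `has_role` cross-link to one hierarchy
#' term at `role_attachment_depth` (or at the deepest available depth).
#' The returned truth ledger records, for every role, the leaf terms
#' planted below its attachment point — computed from the construction
#' edge list, independently of the package's closure functions.
#'
#' @param p a [generator_params()].
#' @return list with `graph` (an [ontology_graph]) and `truth` (list with
#'   `role_attachment`, `role_leaves`, `leaves`, `depth`).
#' @export
generate_dag <- function(p) {
  stopifnot(inherits(p, "generator_params"))
  .with_seed(p$seed, {
    n <- p$n_terms
    ids <- .syn_id("SYN", seq_len(n))
    depth <- integer(n)
    parent_of <- vector("list", n)
    if (n > p$n_roots) {
      for (i in seq(p$n_roots + 1L, n)) {
        k <- sample.int(min(p$max_parents, i - 1L), 1L)
        ps <- sample.int(i - 1L, k)
        parent_of[[i]] <- ps
        depth[[i]] <- 1L + max(depth[ps])
      }
    }
    edges <- do.call(rbind, lapply(seq_len(n), function(i) {
      if (length(parent_of[[i]]) == 0) return(NULL)
      data.frame(child = ids[[i]], parent = ids[parent_of[[i]]],
                 stringsAsFactors = FALSE)
    }))

    # generator-local structures, kept independent of ontology_graph methods
    children_of <- vector("list", n)
    for (i in seq_len(n)) {
      for (ps in parent_of[[i]]) {
        children_of[[ps]] <- c(children_of[[ps]], i)
      }
    }
    is_leaf <- lengths(children_of) == 0
    leaf_descendants <- function(i) {
      stack <- i
      found <- integer()
      seen <- logical(n)
      while (length(stack) > 0) {
        v <- stack[[1]]
        stack <- stack[-1]
        if (seen[[v]]) next
        seen[[v]] <- TRUE
        if (is_leaf[[v]]) found <- c(found, v)
        stack <- c(stack, children_of[[v]])
      }
      sort(unique(found))
    }

    target_depth <- p$role_attachment_depth
    candidates <- which(depth == target_depth)
    if (length(candidates) == 0) candidates <- which(depth == max(depth))
    role_root <- "SYNROLE:0000000"
    role_ids <- .syn_id("SYNROLE", seq_len(p$n_role_terms))
    attach_at <- candidates[sample.int(length(candidates), p$n_role_terms,
                                       replace = length(candidates) < p$n_role_terms)]
    terms <- data.frame(
      id = c(ids, role_root, role_ids),
      label = c(sprintf("synthetic chemical %d", seq_len(n)),
                "synthetic role", sprintf("synthetic role %d",
                                          seq_len(p$n_role_terms))),
      stringsAsFactors = FALSE)
    edges <- rbind(edges, data.frame(child = role_ids, parent = role_root,
                                     stringsAsFactors = FALSE))
    cross <- data.frame(subject = ids[attach_at], relation = "RO:0000087",
                        object = role_ids, stringsAsFactors = FALSE)
    truth <- list(
      role_attachment = stats::setNames(ids[attach_at], role_ids),
      role_leaves = stats::setNames(
        lapply(attach_at, function(i) ids[leaf_descendants(i)]), role_ids),
      leaves = ids[is_leaf],
      depth = stats::setNames(depth, ids))
    list(graph = ontology_graph(terms, edges, cross), truth = truth)
  })
}

#' Generate a synthetic curation table with known ground truth
#'
#' Emits one source fact per drug, chemical facts drawn from the leaf
#' terms of the supplied hierarchy, and adverse-event facts realizing
#' `ae_sharing_spec` exactly (each planted AE is assigned to exactly
#' `k_drugs` of the AE-bearing drugs). The truth ledger records the
#' drug -> chemical map, the expected AE sharing histogram, and — when
#' the DAG truth from [generate_dag()] is supplied — the subset of planted
#' ingredients expected to bear each role through the hierarchy.
#'
#' @param p a [generator_params()].
#' @param g the [ontology_graph] from [generate_dag()].
#' @param dag_truth the truth ledger from [generate_dag()] (optional).
#' @return list with `table` (a `curation_table`) and `truth`.
#' @export
generate_curation <- function(p, g, dag_truth = NULL) {
  stopifnot(inherits(p, "generator_params"), inherits(g, "ontology_graph"))
  .with_seed(p$seed + 1L, {
    chem_ids <- grep("^SYN:", g$terms$id, value = TRUE)
    kids <- g$children[chem_ids]
    leaves <- chem_ids[lengths(kids) == 0]
    if (length(leaves) < p$chemicals_per_drug[[2]]) {
      stop("infeasible params: hierarchy has only ", length(leaves),
           " leaf chemicals")
    }
    labels <- stats::setNames(g$terms$label, g$terms$id)
    drug_names <- sprintf("synthetic drug %02d", seq_len(p$n_drugs))
    categories <- sprintf("synthetic drug category %s", c("A", "B", "C"))
    drug_cat <- categories[(seq_len(p$n_drugs) - 1L) %% length(categories) + 1L]

    rows <- list()
    add_row <- function(...) {
      r <- list(drug = "", category = "", fact_type = "", organism_id = "",
                anatomy_id = "", chemical_label = "", chemical_id = "",
                roles = "", ae_label = "", ae_id = "")
      args <- list(...)
      r[names(args)] <- args
      rows[[length(rows) + 1L]] <<- as.data.frame(r, stringsAsFactors = FALSE)
    }

    drug_chems <- list()
    for (d in seq_len(p$n_drugs)) {
      add_row(drug = drug_names[[d]], category = drug_cat[[d]],
              fact_type = "source", organism_id = .syn_id("SYNTAX", d))
      n_range <- seq(p$chemicals_per_drug[[1]], p$chemicals_per_drug[[2]])
      n_chem <- n_range[sample.int(length(n_range), 1L)]
      chems <- sort(sample(leaves, n_chem))
      drug_chems[[drug_names[[d]]]] <- chems
      for (ch in chems) {
        add_row(drug = drug_names[[d]], category = drug_cat[[d]],
                fact_type = "chemical", chemical_label = labels[[ch]],
                chemical_id = ch)
      }
    }

    ae_drugs <- drug_names[seq_len(p$n_ae_drugs)]
    ae_no <- 0L
    hist_truth <- list()
    for (s in p$ae_sharing_spec) {
      k <- s[[1]]; n_ae <- s[[2]]
      if (n_ae == 0) next
      for (j in seq_len(n_ae)) {
        ae_no <- ae_no + 1L
        lab <- sprintf("synthetic AE %03d", ae_no)
        for (d in sort(sample(ae_drugs, k))) {
          add_row(drug = d, category = drug_cat[[match(d, drug_names)]],
                  fact_type = "ae", ae_label = lab,
                  ae_id = .syn_id("SYNAE", ae_no))
        }
      }
      hist_truth[[as.character(k)]] <- n_ae
    }

    ct <- curation_table(do.call(rbind, rows))
    all_ingredients <- sort(unique(unlist(drug_chems, use.names = FALSE)))
    truth <- list(
      drug_chemicals = drug_chems,
      n_chemical_rows = sum(lengths(drug_chems)),
      ae_histogram = hist_truth,
      unique_aes = ae_no,
      ingredients = all_ingredients)
    if (!is.null(dag_truth)) {
      truth$role_chemicals <- lapply(dag_truth$role_leaves, intersect,
                                     x = all_ingredients)
    }
    list(table = ct, truth = truth)
  })
}
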