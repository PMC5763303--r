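#' Relation configuration for knowledge-graph building
#'
#' Maps the builder's relation names to relation term CURIEs and labels.
#' `has_part` (drug has chemical ingredient), `participates_in` (drug
#' participates in adverse event) and `has_role` (chemical bears a
#' biological/application role) are the standard BFO/RO relations. The
#' relations linking a drug to its source organism and anatomic part are
#' not standardized in this domain, so `produced_by` and `derives_from`
#' are configurable with RO defaults.
#'
#' @param ... overrides: `name = c(curie, label)` pairs.
#' @return a `relation_config`: named list of `list(curie, label)`.
#' @export
relation_config <- function(...) {
  rc <- list(
    has_part = list(curie = "BFO:0000051", label = "has part"),
    participates_in = list(curie = "RO:0000056", label = "participates in"),
    has_role = list(curie = "RO:0000087", label = "has role"),
    produced_by = list(curie = "RO:0003001", label = "produced by"),
    derives_from = list(curie = "RO:0001000", label = "derives from")
  )
  dots <- list(...)
  for (nm in names(dots)) {
    v <- dots[[nm]]
    stopifnot(length(v) == 2)
    rc[[nm]] <- list(curie = curie_normalize(v[[1]]), label = v[[2]])
  }
  curies <- vapply(rc, `[[`, character(1), "curie")
  labels <- vapply(rc, `[[`, character(1), "label")
  if (any(!nzchar(curies)) || any(!nzchar(labels)) || anyDuplicated(curies)) {
    stop("relation_config requires nonempty, unique CURIEs and nonempty labels")
  }
  structure(rc, class = "relation_config")
}

#' Default mapping from curator role names to role terms
#'
#' Curators tag chemical ingredients with role names; these map to ChEBI
#' application-role terms ("anti-inflammatory agent", "antineoplastic
#' agent") for `has_role` assertions.
#'
#' @return named list of `list(curie, label)` keyed by curator role name.
#' @export
default_role_terms <- function() {
  list(
    "anti-inflammatory" = list(curie = "CHEBI:67079",
                               label = "anti-inflammatory agent"),
    "antineoplastic" = list(curie = "CHEBI:35610",
                            label = "antineoplastic agent")
  )
}

.IS_A <- "rdfs:subClassOf"

#' Construct a knowledge graph from triples
#'
#' A `knowledge_graph` is a deduplicated set of subject-predicate-object
#' triples over CURIEs plus a label map. `axiom_kind` distinguishes plain
#' subclass axioms (`"is_a"`) from existential restrictions
#' (`"existential"`, serialized as `subClassOf some` axioms in Turtle and
#' flattened to direct edges in N-Triples).
#'
#' @param triples data.frame with columns `subject`, `predicate`,
#'   `object` and optionally `axiom_kind`.
#' @param labels named character vector mapping CURIEs to labels.
#' @param provenance optional named list (drug term -> source row ids).
#' @return a `knowledge_graph`.
#' @export
knowledge_graph <- function(triples, labels = character(), provenance = list()) {
  if (is.null(triples) || nrow(triples) == 0) {
    triples <- data.frame(subject = character(), predicate = character(),
                          object = character(), axiom_kind = character(),
                          stringsAsFactors = FALSE)
  } else {
    stopifnot(all(c("subject", "predicate", "object") %in% names(triples)))
    if (is.null(triples$axiom_kind)) {
      triples$axiom_kind <- ifelse(triples$predicate == .IS_A, "is_a",
                                   "existential")
    }
    triples <- data.frame(subject = curie_normalize(triples$subject),
                          predicate = curie_normalize(triples$predicate),
                          object = curie_normalize(triples$object),
                          axiom_kind = as.character(triples$axiom_kind),
                          stringsAsFactors = FALSE)
    stopifnot(all(triples$axiom_kind %in% c("is_a", "existential")))
    triples <- unique(triples)
    triples <- triples[order(triples$subject, triples$predicate,
                             triples$object), , drop = FALSE]
    rownames(triples) <- NULL
  }
  if (length(labels) > 0) names(labels) <- curie_normalize(names(labels))
  structure(list(triples = triples, labels = labels, provenance = provenance),
            class = "knowledge_graph")
}

#' @export
print.knowledge_graph <- function(x, ...) {
  terms <- unique(c(x$triples$subject, x$triples$object))
  unlabeled <- setdiff(terms, names(x$labels))
  cat(sprintf("knowledge_graph: %d triples (%d is_a, %d existential), %d terms (%d unlabeled)\n",
              nrow(x$triples), sum(x$triples$axiom_kind == "is_a"),
              sum(x$triples$axiom_kind == "existential"), length(terms),
              length(unlabeled)))
  invisible(x)
}

#' Mint deterministic drug term ids
#'
#' Drug classes get package-local ids in an OCMR-like namespace because
#' the source ontology's IRIs are not published. Ids are a zero-padded
#' 7-digit sequence assigned in sorted-label order, so the same table
#' always yields the same ids.
#'
#' @param labels character vector of drug labels (duplicates allowed; the
#'   id map covers the unique labels).
#' @param namespace CURIE prefix for minted ids.
#' @param start first sequence number.
#' @return named character vector label -> CURIE, in sorted-label order.
#' @export
mint_drug_terms <- function(labels, namespace = "OCMR", start = 1L) {
  stopifnot(is.character(labels))
  if (!grepl("^[A-Za-z][A-Za-z0-9.\\-]*$", namespace)) {
    stop("malformed namespace prefix: ", namespace)
  }
  labels <- sort(unique(labels[nzchar(labels)]), method = "radix")
  ids <- sprintf("%s:%07d", namespace, seq_along(labels) + start - 1L)
  stats::setNames(ids, labels)
}

#' Axiom templates over curation-table columns
#'
#' An `axiom_template` instantiates one existential triple per table row
#' that fills its placeholders, the way a templating tool stamps axioms
#' out of an annotation spreadsheet. The pattern has the form
#' `"{subject_field} relation {object_field}"` where fields are schema
#' columns (plus `drug`, which resolves to the minted drug term and
#' expands multi-drug rows). A `{roles}` object field emits one triple
#' per curator role, resolved through `role_terms`.
#'
#' @param pattern template string, e.g. `"{drug} has_part {chemical_id}"`.
#' @param relation optional relation name; defaults to the middle token
#'   of the pattern.
#' @return an `axiom_template`.
#' @export
axiom_template <- function(pattern, relation = NULL) {
  m <- regmatches(pattern,
    regexec("^\\{([a-z_]+)\\}\\s+([A-Za-z_]+)\\s+\\{([a-z_]+)\\}$", pattern))[[1]]
  if (length(m) == 0) stop("unparseable template pattern: ", pattern)
  fields <- c(.CURATION_COLUMNS, "drug")
  if (!m[[2]] %in% fields || !m[[4]] %in% fields) {
    stop("template placeholder is not a table column: ", pattern)
  }
  structure(list(subject_field = m[[2]],
                 relation = if (is.null(relation)) m[[3]] else relation,
                 object_field = m[[4]]),
            class = "axiom_template")
}

#' Apply an axiom template to a curation table
#'
#' @param tpl an [axiom_template()].
#' @param ct a `curation_table`.
#' @param rc a [relation_config()].
#' @param drug_ids optional named vector label -> CURIE; minted with
#'   [mint_drug_terms()] when absent.
#' @param role_terms role-name map (see [default_role_terms()]), used when
#'   a placeholder is `roles`.
#' @return list with `triples` (existential triples data.frame) and
#'   `skipped` (number of table rows that did not fill the placeholders).
#' @export
apply_template <- function(tpl, ct, rc = relation_config(), drug_ids = NULL,
                           role_terms = default_role_terms()) {
  stopifnot(inherits(tpl, "axiom_template"), inherits(ct, "curation_table"))
  if (is.null(rc[[tpl$relation]])) stop("unknown relation name: ", tpl$relation)
  pred <- rc[[tpl$relation]]$curie
  if (is.null(drug_ids)) {
    drug_ids <- mint_drug_terms(unlist(ct$rows$drugs, use.names = FALSE))
  }
  ex <- .expand_rows(ct)
  resolve <- function(field) {
    if (field == "drug") unname(drug_ids[ex$drug])
    else if (field == "roles") ex$roles
    else ex[[field]]
  }
  s <- resolve(tpl$subject_field)
  o <- resolve(tpl$object_field)
  out <- NULL
  if (tpl$object_field == "roles") {
    keep <- lengths(o) > 0 & nzchar(s)
    if (any(keep)) {
      role_of <- function(r) {
        if (is.null(role_terms[[r]])) stop("unknown curator role: ", r)
        role_terms[[r]]$curie
      }
      out <- do.call(rbind, lapply(which(keep), function(i) {
        data.frame(subject = s[[i]], predicate = pred,
                   object = vapply(o[[i]], role_of, character(1)),
                   stringsAsFactors = FALSE)
      }))
    }
    skipped_rows <- unique(ex$row_id[!keep])
  } else {
    keep <- nzchar(s) & nzchar(o)
    if (any(keep)) {
      out <- data.frame(subject = s[keep], predicate = pred,
                        object = o[keep], stringsAsFactors = FALSE)
    }
    skipped_rows <- setdiff(unique(ex$row_id), unique(ex$row_id[keep]))
  }
  if (!is.null(out)) out$axiom_kind <- "existential"
  if (is.null(out)) {
    out <- data.frame(subject = character(), predicate = character(),
                      object = character(), axiom_kind = character(),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  list(triples = out, skipped = length(skipped_rows))
}

#' Build the drug knowledge graph from a curation table
#'
#' Instantiates the ontology design pattern: each drug becomes a minted
#' class placed under its drug-category class (`is_a`); chemical
#' ingredients attach via `has_part`, adverse events via
#' `participates_in`, source organism and anatomic part via the
#' configured relations (all as existential axioms); curator-assigned
#' roles become `has_role` axioms from the chemical CURIE to the role
#' term; and every supplied ontology slice contributes its is-a edges and
#' cross-links. Two printed drug labels that collapse under
#' [normalize_label()] are rejected as a curation inconsistency.
#'
#' @param ct a `curation_table`.
#' @param ontologies named list of [ontology_graph] slices to import.
#' @param rc a [relation_config()].
#' @param role_terms curator role-name map (see [default_role_terms()]).
#' @param namespace prefix for minted drug/category ids.
#' @return a `knowledge_graph`.
#' @export
build_kg <- function(ct, ontologies = list(), rc = relation_config(),
                     role_terms = default_role_terms(), namespace = "OCMR") {
  stopifnot(inherits(ct, "curation_table"), inherits(rc, "relation_config"))
  drugs <- ct$drugs
  norm <- normalize_label(drugs)
  if (anyDuplicated(norm)) {
    stop("duplicate drug label(s) after normalization: ",
         paste(unique(norm[duplicated(norm)]), collapse = ", "))
  }
  drug_ids <- mint_drug_terms(drugs, namespace)
  ex <- .expand_rows(ct)

  cats <- sort(unique(ex$category[nzchar(ex$category)]), method = "radix")
  cat_ids <- if (length(cats) > 0) {
    mint_drug_terms(cats, namespace, start = length(drug_ids) + 1L)
  } else stats::setNames(character(), character())

  # drug -> category is_a (a drug may appear with its category on any row)
  dc <- unique(data.frame(drug = ex$drug, category = ex$category,
                          stringsAsFactors = FALSE))
  dc <- dc[nzchar(dc$category), , drop = FALSE]
  is_a <- NULL
  if (nrow(dc) > 0) {
    is_a <- data.frame(subject = unname(drug_ids[dc$drug]), predicate = .IS_A,
                       object = unname(cat_ids[dc$category]),
                       axiom_kind = "is_a", stringsAsFactors = FALSE)
  }

  tpl_triples <- lapply(list(
    axiom_template("{drug} has_part {chemical_id}"),
    axiom_template("{drug} participates_in {ae_id}"),
    axiom_template("{drug} produced_by {organism_id}"),
    axiom_template("{drug} derives_from {anatomy_id}"),
    axiom_template("{chemical_id} has_role {roles}")
  ), function(tpl) apply_template(tpl, ct, rc, drug_ids, role_terms)$triples)

  imported <- lapply(ontologies, function(g) {
    rbind(
      if (nrow(g$is_a) > 0)
        data.frame(subject = g$is_a$child, predicate = .IS_A,
                   object = g$is_a$parent, axiom_kind = "is_a",
                   stringsAsFactors = FALSE),
      if (nrow(g$cross_links) > 0)
        data.frame(subject = g$cross_links$subject,
                   predicate = g$cross_links$relation,
                   object = g$cross_links$object, axiom_kind = "existential",
                   stringsAsFactors = FALSE))
  })

  triples <- do.call(rbind, c(list(is_a), tpl_triples, unname(imported)))

  labels <- c(
    stats::setNames(names(drug_ids), unname(drug_ids)),
    stats::setNames(names(cat_ids), unname(cat_ids)),
    stats::setNames(vapply(rc, `[[`, character(1), "label"),
                    vapply(rc, `[[`, character(1), "curie")),
    stats::setNames(vapply(role_terms, `[[`, character(1), "label"),
                    vapply(role_terms, `[[`, character(1), "curie"))
  )
  chem <- ex[ex$fact_type == "chemical" & nzchar(ex$chemical_id) &
               nzchar(ex$chemical_label), , drop = FALSE]
  labels <- c(labels, stats::setNames(chem$chemical_label, chem$chemical_id))
  aes <- ex[ex$fact_type == "ae" & nzchar(ex$ae_id) & nzchar(ex$ae_label), ,
            drop = FALSE]
  labels <- c(labels, stats::setNames(aes$ae_label, aes$ae_id))
  for (g in ontologies) {
    lab <- g$terms$label
    labels <- c(labels, stats::setNames(lab, g$terms$id)[nzchar(lab)])
  }
  labels <- labels[!duplicated(names(labels))]

  prov <- split(ex$row_id, unname(drug_ids[ex$drug]))
  knowledge_graph(triples, labels, prov)
}
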