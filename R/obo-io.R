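#' Read an OBO-flavoured ontology slice
#'
#' Parses the OBO subset used by this package's fixtures and writers:
#' `format-version`, `[Term]` stanzas with `id`, `name`, `synonym`,
#' `is_a`, `relationship` (cross-links such as `has_role`), and
#' `is_obsolete`. `[Typedef]` stanzas are skipped. Ids in either CURIE
#' dialect are normalized to the colon form. The resulting graph is
#' validated: dangling edge targets and is-a cycles are rejected with the
#' offending ids, unparseable lines with their line number.
#'
#' Relationship names are mapped to relation CURIEs via `relations`
#' (default: `has_role` -> `RO:0000087`); a relationship written directly
#' as a CURIE is kept as-is.
#'
#' @param path path to an OBO file.
#' @param relations named character vector mapping relationship names to
#'   relation CURIEs.
#' @return an [ontology_graph].
#' @examples
#' g <- load_obo(system.file("extdata", "toy_taxonomy.obo", package = "ocmrkit"))
#' g
#' @export
load_obo <- function(path, relations = c(has_role = "RO:0000087")) {
  stopifnot(file.exists(path))
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)

  terms <- list()
  edges <- list()
  links <- list()
  cur <- NULL
  in_skipped <- FALSE

  flush_term <- function(cur) {
    if (is.null(cur)) return()
    if (is.null(cur$id)) stop("[Term] stanza without id (line ", cur$start, ")")
    terms[[length(terms) + 1L]] <<- cur
  }
  strip_comment <- function(v) trimws(sub("\\s*!.*$", "", v))

  for (i in seq_along(lines)) {
    line <- trimws(lines[[i]])
    if (line == "" || startsWith(line, "!")) next
    if (startsWith(line, "[")) {
      flush_term(cur)
      cur <- NULL
      in_skipped <- !identical(line, "[Term]")
      if (!in_skipped) cur <- list(start = i, synonyms = character(),
                                   obsolete = FALSE)
      next
    }
    if (in_skipped) next
    m <- regmatches(line, regexec("^([A-Za-z_-]+):\\s*(.*)$", line))[[1]]
    if (length(m) == 0) stop("unparseable line ", i, ": ", line)
    tag <- m[[2]]
    val <- m[[3]]
    if (is.null(cur)) {
      # header line (format-version, date, ...): accepted and ignored
      next
    }
    if (tag == "id") {
      cur$id <- curie_normalize(strip_comment(val))
    } else if (tag == "name") {
      cur$label <- strip_comment(val)
    } else if (tag == "synonym") {
      syn <- regmatches(val, regexec('^"([^"]*)"', val))[[1]]
      if (length(syn) == 0) stop("unparseable synonym at line ", i, ": ", line)
      cur$synonyms <- c(cur$synonyms, syn[[2]])
    } else if (tag == "is_a") {
      edges[[length(edges) + 1L]] <- c(child = NA, parent = strip_comment(val),
                                       idx = length(terms) + 1L)
    } else if (tag == "relationship") {
      v <- strsplit(strip_comment(val), "\\s+")[[1]]
      if (length(v) != 2) stop("unparseable relationship at line ", i, ": ", line)
      rel <- if (v[[1]] %in% names(relations)) relations[[v[[1]]]] else v[[1]]
      links[[length(links) + 1L]] <- c(subject = NA, relation = rel,
                                       object = v[[2]], idx = length(terms) + 1L)
    } else if (tag == "is_obsolete") {
      cur$obsolete <- identical(strip_comment(val), "true")
    } else {
      stop("unsupported tag '", tag, "' at line ", i, ": ", line)
    }
  }
  flush_term(cur)

  if (length(terms) == 0) {
    return(ontology_graph(data.frame(id = character(), label = character(),
                                     stringsAsFactors = FALSE)))
  }
  term_df <- data.frame(
    id = vapply(terms, function(t) t$id, character(1)),
    label = vapply(terms, function(t) if (is.null(t$label)) "" else t$label,
                   character(1)),
    obsolete = vapply(terms, function(t) t$obsolete, logical(1)),
    stringsAsFactors = FALSE)
  term_df$synonyms <- lapply(terms, function(t) t$synonyms)

  owner <- function(idx) term_df$id[[as.integer(idx)]]
  is_a <- NULL
  if (length(edges) > 0) {
    is_a <- data.frame(
      child = vapply(edges, function(e) owner(e[["idx"]]), character(1)),
      parent = vapply(edges, function(e) e[["parent"]], character(1)),
      stringsAsFactors = FALSE)
  }
  cross <- NULL
  if (length(links) > 0) {
    cross <- data.frame(
      subject = vapply(links, function(e) owner(e[["idx"]]), character(1)),
      relation = vapply(links, function(e) e[["relation"]], character(1)),
      object = vapply(links, function(e) e[["object"]], character(1)),
      stringsAsFactors = FALSE)
  }
  ontology_graph(term_df, is_a, cross)
}

#' Write an ontology graph as an OBO-flavoured file
#'
#' Writes the same dialect [load_obo()] reads: terms sorted by CURIE,
#' `is_a` and `relationship` lines sorted within each stanza, so output is
#' byte-stable for a given graph and round-trips exactly.
#'
#' @param g an [ontology_graph].
#' @param path output file path.
#' @param relations named character vector; relation CURIEs matching a
#'   value are written with the corresponding relationship name.
#' @return `path`, invisibly.
#' @export
write_obo <- function(g, path, relations = c(has_role = "RO:0000087")) {
  stopifnot(inherits(g, "ontology_graph"))
  rel_name <- stats::setNames(names(relations), relations)
  out <- c("format-version: 1.2", "")
  ord <- order(g$terms$id)
  for (i in ord) {
    id <- g$terms$id[[i]]
    out <- c(out, "[Term]", paste0("id: ", id))
    if (nzchar(g$terms$label[[i]])) out <- c(out, paste0("name: ", g$terms$label[[i]]))
    for (s in sort(g$terms$synonyms[[i]])) {
      out <- c(out, sprintf('synonym: "%s" EXACT []', s))
    }
    for (p in sort(g$is_a$parent[g$is_a$child == id])) {
      out <- c(out, paste0("is_a: ", p))
    }
    cl <- g$cross_links[g$cross_links$subject == id, , drop = FALSE]
    if (nrow(cl) > 0) {
      cl <- cl[order(cl$relation, cl$object), , drop = FALSE]
      nm <- ifelse(cl$relation %in% names(rel_name), rel_name[cl$relation],
                   cl$relation)
      out <- c(out, paste0("relationship: ", nm, " ", cl$object))
    }
    if (g$terms$obsolete[[i]]) out <- c(out, "is_obsolete: true")
    out <- c(out, "")
  }
  writeLines(out, path, useBytes = TRUE)
  invisible(path)
}
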