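.TTL_PREFIXES <- c(
  "@prefix obo: <http://purl.obolibrary.org/obo/> .",
  "@prefix owl: <http://www.w3.org/2002/07/owl#> .",
  "@prefix rdf: <http://www.w3.org/1999/02/22-rdf-syntax-ns#> .",
  "@prefix rdfs: <http://www.w3.org/2000/01/rdf-schema#> ."
)

# prefixed-name form used in Turtle output: W3C namespaces keep their
# prefix, everything else goes through the OBO PURL namespace
.ttl_name <- function(curie) {
  prefix <- sub(":.*$", "", curie)
  local <- sub("^[^:]*:", "", curie)
  ifelse(prefix %in% c("rdf", "rdfs", "owl"), paste0(prefix, ":", local),
         paste0("obo:", prefix, "_", local))
}

.escape_literal <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  gsub('"', '\\"', x, fixed = TRUE)
}
.unescape_literal <- function(x) {
  x <- gsub('\\"', '"', x, fixed = TRUE)
  gsub("\\\\", "\\", x, fixed = TRUE)
}

#' Serialize a knowledge graph as Turtle (OWL) or N-Triples
#'
#' `export_turtle()` writes the ontology view: labels as `rdfs:label`,
#' `is_a` triples as plain `rdfs:subClassOf`, and existential triples as
#' the standard `rdfs:subClassOf [ a owl:Restriction ; owl:onProperty R ;
#' owl:someValuesFrom O ]` pattern, subjects sorted by IRI — byte-stable
#' for a given graph. `export_ntriples()` writes the materialized,
#' query-ready view: existential axioms flattened to direct predicate
#' edges (plus `rdfs:label` literal triples), one sorted line per triple.
#'
#' @param kg a [knowledge_graph].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
export_turtle <- function(kg, path) {
  stopifnot(inherits(kg, "knowledge_graph"))
  tr <- kg$triples
  subjects <- sort(unique(curie_to_iri(unique(c(tr$subject,
                                                names(kg$labels))))),
                   method = "radix")
  lines <- c(.TTL_PREFIXES, "")
  for (iri in subjects) {
    s <- iri_to_curie(iri)
    sn <- .ttl_name(s)
    if (s %in% names(kg$labels)) {
      lines <- c(lines, sprintf('%s rdfs:label "%s" .', sn,
                                .escape_literal(kg$labels[[s]])))
    }
    st <- tr[tr$subject == s, , drop = FALSE]
    st <- st[order(st$predicate, st$object), , drop = FALSE]
    isa <- st[st$axiom_kind == "is_a", , drop = FALSE]
    lines <- c(lines, sprintf("%s rdfs:subClassOf %s .", sn,
                              .ttl_name(isa$object)))
    exi <- st[st$axiom_kind == "existential", , drop = FALSE]
    lines <- c(lines, sprintf(
      "%s rdfs:subClassOf [ a owl:Restriction ; owl:onProperty %s ; owl:someValuesFrom %s ] .",
      sn, .ttl_name(exi$predicate), .ttl_name(exi$object)))
  }
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname export_turtle
#' @export
export_ntriples <- function(kg, path) {
  stopifnot(inherits(kg, "knowledge_graph"))
  tr <- kg$triples
  lines <- sprintf("<%s> <%s> <%s> .", curie_to_iri(tr$subject),
                   curie_to_iri(tr$predicate), curie_to_iri(tr$object))
  if (length(kg$labels) > 0) {
    lines <- c(lines, sprintf(
      '<%s> <http://www.w3.org/2000/01/rdf-schema#label> "%s" .',
      curie_to_iri(names(kg$labels)), .escape_literal(unname(kg$labels))))
  }
  writeLines(sort(unique(lines), method = "radix"), path, useBytes = TRUE)
  invisible(path)
}

#' Read a knowledge graph back from Turtle or N-Triples
#'
#' Readers for the exact dialects the exporters write (not general RDF
#' parsers). `read_turtle()` recovers is_a vs existential axiom kinds from
#' the restriction pattern; `read_ntriples()` classifies `rdfs:subClassOf`
#' edges as `is_a` and everything else as materialized existential edges.
#' Both recover the label map. export -> read round-trips the triple set
#' exactly.
#'
#' @param path input file path.
#' @return a [knowledge_graph].
#' @export
read_turtle <- function(path) {
  stopifnot(file.exists(path))
  lines <- trimws(readLines(path, encoding = "UTF-8", warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "@prefix")]
  name_to_curie <- function(x) {
    obo <- startsWith(x, "obo:")
    x[obo] <- sub("^obo:", "", x[obo])
    curie_normalize(x)
  }
  triples <- list()
  labels <- character()
  re_label <- '^(\\S+) rdfs:label "((\\\\.|[^"])*)" \\.$'
  re_isa <- "^(\\S+) rdfs:subClassOf (obo:\\S+|[a-z]+:\\S+) \\.$"
  re_exi <- "^(\\S+) rdfs:subClassOf \\[ a owl:Restriction ; owl:onProperty (\\S+) ; owl:someValuesFrom (\\S+) \\] \\.$"
  for (line in lines) {
    m <- regmatches(line, regexec(re_label, line))[[1]]
    if (length(m) > 0) {
      labels[[name_to_curie(m[[2]])]] <- .unescape_literal(m[[3]])
      next
    }
    m <- regmatches(line, regexec(re_exi, line))[[1]]
    if (length(m) > 0) {
      triples[[length(triples) + 1L]] <- data.frame(
        subject = name_to_curie(m[[2]]), predicate = name_to_curie(m[[3]]),
        object = name_to_curie(m[[4]]), axiom_kind = "existential",
        stringsAsFactors = FALSE)
      next
    }
    m <- regmatches(line, regexec(re_isa, line))[[1]]
    if (length(m) > 0) {
      triples[[length(triples) + 1L]] <- data.frame(
        subject = name_to_curie(m[[2]]), predicate = "rdfs:subClassOf",
        object = name_to_curie(m[[3]]), axiom_kind = "is_a",
        stringsAsFactors = FALSE)
      next
    }
    stop("unparseable Turtle line: ", line)
  }
  knowledge_graph(do.call(rbind, triples), labels)
}

#' @rdname read_turtle
#' @export
read_ntriples <- function(path) {
  stopifnot(file.exists(path))
  lines <- trimws(readLines(path, encoding = "UTF-8", warn = FALSE))
  lines <- lines[nzchar(lines)]
  re_iri <- "^<(\\S+)> <(\\S+)> <(\\S+)> \\.$"
  re_lit <- '^<(\\S+)> <(\\S+)> "((\\\\.|[^"])*)" \\.$'
  triples <- list()
  labels <- character()
  for (line in lines) {
    m <- regmatches(line, regexec(re_iri, line))[[1]]
    if (length(m) > 0) {
      triples[[length(triples) + 1L]] <- data.frame(
        subject = iri_to_curie(m[[2]]), predicate = iri_to_curie(m[[3]]),
        object = iri_to_curie(m[[4]]), stringsAsFactors = FALSE)
      next
    }
    m <- regmatches(line, regexec(re_lit, line))[[1]]
    if (length(m) > 0) {
      if (iri_to_curie(m[[3]]) == "rdfs:label") {
        labels[[iri_to_curie(m[[2]])]] <- .unescape_literal(m[[4]])
      }
      next
    }
    stop("unparseable N-Triples line: ", line)
  }
  knowledge_graph(do.call(rbind, triples), labels)
}
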