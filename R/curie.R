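#' Normalize a term identifier to its canonical CURIE form
#'
#' Ontology identifiers occur in two dialects: the colon CURIE used by OBO
#' flat files (`CHEBI:9747`) and the underscore form used inside OBO PURL
#' IRIs and in some printed tables (`CHEBI_9747`). Both normalize to the
#' colon CURIE, which is the canonical internal form throughout the package.
#' Full OBO PURL IRIs (`http://purl.obolibrary.org/obo/CHEBI_9747`) are also
#' accepted.
#'
#' @param x character vector of identifiers in either dialect (or OBO PURL
#'   IRIs).
#' @return character vector of canonical CURIEs (`PREFIX:LOCAL`).
#' @examples
#' curie_normalize(c("CHEBI_9747", "CHEBI:9747"))
#' @export
curie_normalize <- function(x) {
  stopifnot(is.character(x))
  x <- trimws(x)
  iri <- grepl("^https?://", x)
  x[iri] <- sub("^https?://purl\\.obolibrary\\.org/obo/", "", x[iri])
  # underscore dialect: replace the LAST underscore separator between a
  # non-empty prefix and local part, but only when no colon is present
  no_colon <- !grepl(":", x, fixed = TRUE) & grepl("_", x, fixed = TRUE)
  x[no_colon] <- sub("_", ":", x[no_colon])
  bad <- !grepl("^[A-Za-z][A-Za-z0-9.\\-]*:\\S+$", x)
  if (any(bad)) {
    stop("malformed term identifier(s): ", paste(x[bad], collapse = ", "))
  }
  x
}

#' Convert between CURIEs and OBO PURL IRIs
#'
#' `curie_to_iri()` maps `CHEBI:9747` to
#' `http://purl.obolibrary.org/obo/CHEBI_9747`; `iri_to_curie()` inverts it.
#' The two conversions are lossless for OBO-style identifiers. Identifiers
#' in reserved W3C namespaces (`rdf`, `rdfs`, `owl`) map to their standard
#' IRIs instead of OBO PURLs.
#'
#' @param x character vector of CURIEs or IRIs.
#' @return character vector of IRIs (`curie_to_iri`) or CURIEs
#'   (`iri_to_curie`).
#' @export
curie_to_iri <- function(x) {
  x <- curie_normalize(x)
  if (length(x) == 0) return(character())
  prefix <- sub(":.*$", "", x)
  local <- sub("^[^:]*:", "", x)
  ns <- c(
    rdf  = "http://www.w3.org/1999/02/22-rdf-syntax-ns#",
    rdfs = "http://www.w3.org/2000/01/rdf-schema#",
    owl  = "http://www.w3.org/2002/07/owl#"
  )
  out <- paste0("http://purl.obolibrary.org/obo/", prefix, "_", local)
  w3c <- prefix %in% names(ns)
  out[w3c] <- paste0(ns[prefix[w3c]], local[w3c])
  out
}

#' @rdname curie_to_iri
#' @export
iri_to_curie <- function(x) {
  stopifnot(is.character(x))
  x <- sub("^http://www\\.w3\\.org/1999/02/22-rdf-syntax-ns#", "rdf:", x)
  x <- sub("^http://www\\.w3\\.org/2000/01/rdf-schema#", "rdfs:", x)
  x <- sub("^http://www\\.w3\\.org/2002/07/owl#", "owl:", x)
  curie_normalize(x)
}
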