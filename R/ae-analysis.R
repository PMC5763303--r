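#' Adverse-event profile of a curation table
#'
#' Groups AE facts by [normalize_label()]ed AE label (curation sources
#' vary in case and whitespace, and some AEs lack ontology ids, so label
#' grouping is the default; set `by = "curie"` to group by OAE CURIE
#' instead, dropping id-less rows). Within a drug, a repeated AE counts
#' once.
#'
#' @param ct a `curation_table`.
#' @param by `"label"` (default) or `"curie"`.
#' @return an `ae_profile`: list with `aes` (named list AE -> sorted drug
#'   labels), `total_ae_rows` (table lines with an AE fact),
#'   `total_drug_ae_pairs` (deduplicated (drug, AE) pairs) and
#'   `unique_aes`.
#' @export
ae_profile <- function(ct, by = c("label", "curie")) {
  stopifnot(inherits(ct, "curation_table"))
  by <- match.arg(by)
  ex <- .expand_rows(ct)
  aes <- ex[ex$fact_type == "ae", , drop = FALSE]
  total_rows <- sum(ct$rows$fact_type == "ae")
  key <- if (by == "label") normalize_label(aes$ae_label) else aes$ae_id
  keep <- nzchar(key)
  pairs <- unique(data.frame(ae = key[keep], drug = aes$drug[keep],
                             stringsAsFactors = FALSE))
  groups <- lapply(split(pairs$drug, pairs$ae), function(d) sort(unique(d)))
  groups <- groups[order(names(groups), method = "radix")]
  structure(list(aes = groups, total_ae_rows = total_rows,
                 total_drug_ae_pairs = nrow(pairs),
                 unique_aes = length(groups), by = by),
            class = "ae_profile")
}

#' @export
print.ae_profile <- function(x, ...) {
  cat(sprintf("ae_profile (%s): %d unique AEs, %d (drug, AE) pairs, %d AE rows\n",
              x$by, x$unique_aes, x$total_drug_ae_pairs, x$total_ae_rows))
  invisible(x)
}

#' Cross-drug AE sharing
#'
#' `sharing_histogram()` partitions the AEs of a profile by the exact
#' number of drugs reporting them; `aes_shared_by_at_least()` returns the
#' AEs reported by at least `k` drugs. The histogram classes are disjoint,
#' cover all AEs, and their sizes sum to `unique_aes`.
#'
#' @param p an [ae_profile()].
#' @param k minimum number of sharing drugs (>= 1).
#' @return `sharing_histogram()`: named list, `"k"` -> sorted AE keys
#'   shared by exactly `k` drugs; `aes_shared_by_at_least()`: sorted AE
#'   keys.
#' @export
sharing_histogram <- function(p) {
  stopifnot(inherits(p, "ae_profile"))
  counts <- lengths(p$aes)
  out <- split(names(p$aes), counts)
  lapply(out[order(as.integer(names(out)))], sort)
}

#' @rdname sharing_histogram
#' @export
aes_shared_by_at_least <- function(p, k) {
  stopifnot(inherits(p, "ae_profile"))
  if (!is.numeric(k) || length(k) != 1 || k < 1) {
    stop("k must be a count >= 1")
  }
  sort(names(p$aes)[lengths(p$aes) >= k])
}

#' Classify AEs into designated top-level ontology classes
#'
#' Assigns each AE term to every designated class among its
#' ancestors-or-self in the OAE slice (body-system groupings such as
#' "behavioral and neurological AE", "digestive system AE", "skin AE").
#' Because the hierarchy is a DAG an AE may fall in several designated
#' classes; AEs matching none are reported under `unclassified`.
#'
#' @param g_oae an [ontology_graph] of the AE ontology slice.
#' @param aes character vector of AE term CURIEs, declared in `g_oae`.
#' @param designated character vector of designated class CURIEs,
#'   declared in `g_oae` (unknown classes are an error).
#' @return list with `classes` (designated class -> sorted member AEs)
#'   and `unclassified`.
#' @export
top_level_ae_classes <- function(g_oae, aes, designated) {
  aes <- unique(.check_terms(g_oae, aes))
  designated <- unique(.check_terms(g_oae, designated))
  anc <- lapply(aes, function(a) c(a, ancestors(g_oae, a)))
  names(anc) <- aes
  classes <- lapply(designated, function(d) {
    sort(aes[vapply(anc, function(x) d %in% x, logical(1))])
  })
  names(classes) <- designated
  list(classes = classes,
       unclassified = sort(setdiff(aes, unlist(classes, use.names = FALSE))))
}
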