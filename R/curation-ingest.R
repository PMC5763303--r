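.CURATION_COLUMNS <- c("drug", "category", "fact_type", "organism_id",
                       "anatomy_id", "chemical_label", "chemical_id",
                       "roles", "ae_label", "ae_id")

#' Normalize a drug, chemical or adverse-event label
#'
#' Trims, collapses internal whitespace, case-folds, and drops a trailing
#' "TCD" token (the decoction-piece suffix that drug tables append to drug
#' names but that is ignored when matching, e.g. "Common Floweringqince
#' Fruit TCD" and "common floweringqince fruit" are the same drug).
#'
#' @param s character vector.
#' @return normalized character vector.
#' @examples
#' normalize_label("Common Floweringqince Fruit TCD")
#' normalize_label("  Mulberry   Twig ")
#' @export
normalize_label <- function(s) {
  stopifnot(is.character(s))
  s <- tolower(trimws(gsub("[[:space:]]+", " ", s)))
  sub(" tcd$", "", s)
}

.norm_curie_col <- function(x, col, line_no) {
  x <- trimws(x)
  out <- x
  for (i in which(nzchar(x))) {
    v <- tryCatch(curie_normalize(x[[i]]), error = function(e) NULL)
    if (is.null(v)) {
      stop("malformed CURIE in column '", col, "' at row ", line_no[[i]],
           ": ", x[[i]])
    }
    out[[i]] <- v
  }
  out
}

#' Parse the curated drug annotation table
#'
#' Reads the long-format TSV that records one annotated fact per line for
#' each traditional Chinese drug (TCD): its source organism and anatomic
#' part (`fact_type = "source"`), a chemical ingredient with optional
#' ChEBI CURIE and curator-assigned roles (`"chemical"`), or an adverse
#' event with optional OAE CURIE (`"ae"`). The `drug` column may list
#' several drugs separated by `;` (as printed ingredient tables do); the
#' row is kept intact and expanded on demand downstream. `#` lines are
#' comments; `roles` are split on `;`; CURIEs are normalized to the colon
#' dialect.
#'
#' A row may carry exactly one kind of fact: mixing, say, a chemical id
#' with an AE label is rejected with the offending line number, as are
#' missing columns, malformed CURIEs and unknown fact types.
#'
#' @param path path to the TSV file.
#' @return a `curation_table`: list with `rows` (data.frame, one row per
#'   table line; `drugs` and `roles` are list columns) and `drugs` (sorted
#'   unique drug labels as printed).
#' @export
parse_curation_table <- function(path) {
  stopifnot(file.exists(path))
  raw <- utils::read.delim(path, comment.char = "#", colClasses = "character",
                           stringsAsFactors = FALSE, check.names = FALSE,
                           na.strings = NULL, fileEncoding = "UTF-8")
  missing <- setdiff(.CURATION_COLUMNS, names(raw))
  if (length(missing) > 0) {
    stop("missing column(s): ", paste(missing, collapse = ", "))
  }
  raw <- raw[, .CURATION_COLUMNS, drop = FALSE]
  curation_table(raw)
}

#' Construct a curation table from a data.frame
#'
#' Validates and types raw rows with the columns of
#' [parse_curation_table()]'s schema.
#'
#' @param rows data.frame with the ten schema columns (character).
#' @return a `curation_table`.
#' @export
curation_table <- function(rows) {
  stopifnot(is.data.frame(rows),
            all(.CURATION_COLUMNS %in% names(rows)))
  rows <- rows[, .CURATION_COLUMNS, drop = FALSE]
  for (col in .CURATION_COLUMNS) rows[[col]] <- trimws(as.character(rows[[col]]))
  n <- nrow(rows)
  line <- seq_len(n)

  if (any(!nzchar(rows$drug))) {
    stop("empty drug label at row ", paste(line[!nzchar(rows$drug)], collapse = ", "))
  }
  bad_ft <- !rows$fact_type %in% c("source", "chemical", "ae")
  if (any(bad_ft)) {
    stop("unknown fact_type at row ", paste(line[bad_ft], collapse = ", "),
         ": ", paste(unique(rows$fact_type[bad_ft]), collapse = ", "))
  }
  for (col in c("organism_id", "anatomy_id", "chemical_id", "ae_id")) {
    rows[[col]] <- .norm_curie_col(rows[[col]], col, line)
  }

  has_chem <- nzchar(rows$chemical_label) | nzchar(rows$chemical_id)
  has_ae <- nzchar(rows$ae_label) | nzchar(rows$ae_id)
  has_src <- nzchar(rows$organism_id) | nzchar(rows$anatomy_id)
  kinds <- has_chem + has_ae + has_src
  mismatch <- kinds > 1 |
    (rows$fact_type == "chemical" & (has_ae | has_src | !has_chem)) |
    (rows$fact_type == "ae" & (has_chem | has_src | !has_ae)) |
    (rows$fact_type == "source" & (has_chem | has_ae | !has_src))
  if (any(mismatch)) {
    stop("row carries fields inconsistent with its fact_type at row ",
         paste(line[mismatch], collapse = ", "))
  }
  roles <- lapply(strsplit(rows$roles, ";", fixed = TRUE),
                  function(r) sort(unique(trimws(r[nzchar(trimws(r))]))))
  if (any(lengths(roles) > 0 & rows$fact_type != "chemical")) {
    stop("roles present on a non-chemical row at row ",
         paste(line[lengths(roles) > 0 & rows$fact_type != "chemical"],
               collapse = ", "))
  }
  rows$roles <- roles
  rows$drugs <- lapply(strsplit(rows$drug, ";", fixed = TRUE),
                       function(d) trimws(d[nzchar(trimws(d))]))
  rownames(rows) <- NULL
  structure(list(rows = rows,
                 drugs = sort(unique(unlist(rows$drugs, use.names = FALSE)))),
            class = "curation_table")
}

#' @export
print.curation_table <- function(x, ...) {
  ft <- table(factor(x$rows$fact_type, levels = c("source", "chemical", "ae")))
  cat(sprintf("curation_table: %d rows (%d source, %d chemical, %d ae), %d drugs\n",
              nrow(x$rows), ft[["source"]], ft[["chemical"]], ft[["ae"]],
              length(x$drugs)))
  invisible(x)
}

# one row per (single drug, fact)
.expand_rows <- function(ct) {
  rows <- ct$rows
  k <- lengths(rows$drugs)
  out <- rows[rep(seq_len(nrow(rows)), k), , drop = FALSE]
  out$drug <- unlist(rows$drugs, use.names = FALSE)
  out$row_id <- rep(seq_len(nrow(rows)), k)
  rownames(out) <- NULL
  out
}

#' Write a curation table back to TSV
#'
#' Inverse of [parse_curation_table()]: parse -> write -> parse is the
#' identity on rows.
#'
#' @param ct a `curation_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_curation_table <- function(ct, path) {
  stopifnot(inherits(ct, "curation_table"))
  out <- ct$rows[, setdiff(.CURATION_COLUMNS, "roles"), drop = FALSE]
  out$roles <- vapply(ct$rows$roles, paste, character(1), collapse = ";")
  out <- out[, .CURATION_COLUMNS, drop = FALSE]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Validate a curation table and tally its contents
#'
#' Computes per-drug and global counts and checks table-level invariants.
#' Counts: `n_chemical_rows` is the number of ingredient entries (table
#' lines with a chemical fact, a multi-drug line counted once, matching a
#' printed ingredient table's numbering); `n_chemical_facts` expands drug
#' lists to (drug, chemical) pairs; `n_unique_chemical_ids` deduplicates
#' by CURIE (entries without a ChEBI id are excluded, mirroring curation
#' practice where many chemicals lack ids); AE uniqueness is by
#' [normalize_label()]. A drug without a source fact is an error; a CURIE
#' absent from a supplied ontology slice of the same prefix is a warning.
#'
#' @param ct a `curation_table`.
#' @param ontologies named list of [ontology_graph] slices (names are
#'   informational; CURIEs are matched to a slice by prefix).
#' @return a `validation_report`: list with `per_drug` (data.frame),
#'   `global` (named list of counts), `errors`, `warnings`. The table is
#'   accepted downstream iff `errors` is empty.
#' @export
validate_curation <- function(ct, ontologies = list()) {
  stopifnot(inherits(ct, "curation_table"))
  ex <- .expand_rows(ct)
  errors <- character()
  warnings <- character()

  drugs <- ct$drugs
  chem <- ex[ex$fact_type == "chemical", , drop = FALSE]
  aes <- ex[ex$fact_type == "ae", , drop = FALSE]
  src <- ex[ex$fact_type == "source", , drop = FALSE]

  no_source <- setdiff(drugs, unique(src$drug))
  if (length(no_source) > 0) {
    errors <- c(errors, paste0("drug without a source fact: ",
                               paste(sort(no_source), collapse = ", ")))
  }

  per_drug <- data.frame(
    drug = drugs,
    n_chemicals = vapply(drugs, function(d) sum(chem$drug == d), integer(1)),
    n_chemicals_with_id = vapply(drugs, function(d)
      sum(chem$drug == d & nzchar(chem$chemical_id)), integer(1)),
    n_unique_chemical_ids = vapply(drugs, function(d)
      length(unique(chem$chemical_id[chem$drug == d & nzchar(chem$chemical_id)])),
      integer(1)),
    n_aes = vapply(drugs, function(d) sum(aes$drug == d), integer(1)),
    stringsAsFactors = FALSE)
  rownames(per_drug) <- NULL

  no_id <- sum(ct$rows$fact_type == "chemical" & !nzchar(ct$rows$chemical_id))
  if (no_id > 0) {
    warnings <- c(warnings, paste0(no_id,
      " chemical entr(ies) without a ChEBI id are excluded from CURIE-level analyses"))
  }

  if (length(ontologies) > 0) {
    all_ids <- unique(c(chem$chemical_id, aes$ae_id, src$organism_id,
                        src$anatomy_id))
    all_ids <- all_ids[nzchar(all_ids)]
    for (nm in names(ontologies)) {
      g <- ontologies[[nm]]
      prefixes <- unique(sub(":.*$", "", g$terms$id))
      covered <- all_ids[sub(":.*$", "", all_ids) %in% prefixes]
      absent <- setdiff(covered, g$terms$id)
      if (length(absent) > 0) {
        warnings <- c(warnings, paste0("CURIE(s) not found in ontology '", nm,
          "': ", paste(sort(absent), collapse = ", ")))
      }
    }
  }

  global <- list(
    n_rows = nrow(ct$rows),
    n_drugs = length(drugs),
    n_chemical_rows = sum(ct$rows$fact_type == "chemical"),
    n_chemical_facts = nrow(chem),
    n_unique_chemical_ids = length(unique(chem$chemical_id[nzchar(chem$chemical_id)])),
    n_ae_rows = sum(ct$rows$fact_type == "ae"),
    n_drug_ae_pairs = nrow(unique(data.frame(d = aes$drug,
                                             a = normalize_label(aes$ae_label)))),
    n_unique_ae_labels = length(unique(normalize_label(
      aes$ae_label[nzchar(aes$ae_label)])))
  )
  structure(list(per_drug = per_drug, global = global, errors = errors,
                 warnings = warnings),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf(
    "validation_report: %d drugs, %d chemical entries (%d unique CURIEs), %d AE rows (%d unique labels)\n",
    x$global$n_drugs, x$global$n_chemical_rows, x$global$n_unique_chemical_ids,
    x$global$n_ae_rows, x$global$n_unique_ae_labels))
  if (length(x$errors)) cat("errors:\n", paste0("  - ", x$errors, "\n"), sep = "")
  if (length(x$warnings)) cat("warnings:\n", paste0("  - ", x$warnings, "\n"), sep = "")
  invisible(x)
}
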