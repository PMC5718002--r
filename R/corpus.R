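#' Reference record tables
#'
#' Two tibble shapes carry bibliographic records through the pipeline:
#'
#' * **records** — the review's combined, *non-deduplicated* library, one row
#'   per retrieval event: `record_id`, `first_author_surname`,
#'   `second_author_surname` (may be `NA`), `year`, `title`, `database`
#'   (canonical token of the database whose search produced the row). The
#'   same work retrieved by three databases occupies three rows with three
#'   distinct record ids, as in a reference manager library saved without
#'   deduplication.
#' * **includes** — the review's included references, one row per included
#'   study: same bibliographic columns plus `retrieved_by` (list-column of
#'   canonical tokens; empty when the study was found by other search
#'   methods) and `is_included = TRUE`.
#'
#' @name reference-records
NULL

records_cols <- c("record_id", "first_author_surname", "second_author_surname",
                  "year", "title", "database")

empty_records <- function() {
  tibble(record_id = character(), first_author_surname = character(),
         second_author_surname = character(), year = integer(),
         title = character(), database = character())
}

empty_includes <- function() {
  tibble(record_id = character(), first_author_surname = character(),
         second_author_surname = character(), year = integer(),
         title = character(), retrieved_by = list(), is_included = logical())
}

as_records <- function(df) {
  df <- as_tibble(df)
  if (!"second_author_surname" %in% names(df)) df$second_author_surname <- NA_character_
  missing <- setdiff(records_cols, names(df))
  if (length(missing)) {
    sr_abort("missing_field", sprintf("Record table lacks column(s): %s",
                                      paste(missing, collapse = ", ")))
  }
  df$year <- as.integer(df$year)
  df[records_cols]
}

as_includes <- function(df) {
  df <- as_tibble(df)
  if (!"second_author_surname" %in% names(df)) df$second_author_surname <- NA_character_
  if (!"retrieved_by" %in% names(df)) df$retrieved_by <- replicate(nrow(df), character(), simplify = FALSE)
  if (!is.list(df$retrieved_by)) {
    df$retrieved_by <- lapply(strsplit(ifelse(is.na(df$retrieved_by), "", df$retrieved_by), ";"),
                              function(x) x[nzchar(x)])
  }
  df$is_included <- TRUE
  df$year <- as.integer(df$year)
  df[c("record_id", "first_author_surname", "second_author_surname", "year",
       "title", "retrieved_by", "is_included")]
}

#' Construct a single-review dataset
#'
#' Bundles one systematic review's search documentation: the databases
#' searched, the number of records each search retrieved (recorded at search
#' time, before deduplication), optionally the full record-level library,
#' the review's included references, and free-form metadata (e.g. `domain`,
#' `study_type_limit`). All invariants are enforced at construction:
#' result counts and record/include provenance may only name searched
#' databases, record ids must be unique, years plausible, and when records
#' are present their per-database tallies must equal `result_counts`.
#'
#' @param review_id Unique review identifier.
#' @param searched_databases Character vector of canonical database tokens.
#' @param includes Includes table (see [reference-records]).
#' @param records Optional record-level library table.
#' @param result_counts Named integer vector, database -> records retrieved.
#'   Derived from `records` when omitted and records are present.
#' @param metadata Named list; recognised keys include `department`, `domain`
#'   (therapy, etiology, epidemiology, diagnosis, management, prognosis) and
#'   `study_type_limit`.
#' @return A `review_dataset`.
#' @export
review_dataset <- function(review_id, searched_databases, includes,
                           records = NULL, result_counts = NULL,
                           metadata = list()) {
  searched <- unique(as.character(searched_databases))
  includes <- as_includes(includes)
  if (!is.null(records)) records <- as_records(records)
  if (is.null(result_counts)) {
    result_counts <- if (is.null(records)) integer() else
      vapply(split(records$record_id, factor(records$database, levels = searched)),
             length, integer(1))
  }
  rc <- as.integer(result_counts)
  names(rc) <- names(result_counts)
  x <- structure(list(review_id = as.character(review_id),
                      searched_databases = searched,
                      result_counts = rc,
                      records = records,
                      includes = includes,
                      metadata = as.list(metadata)),
                 class = "review_dataset")
  validate_review_dataset(x)
}

validate_review_dataset <- function(x) {
  fail <- function(msg) {
    sr_abort("validation", sprintf("Review %s: %s", sQuote(x$review_id), msg))
  }
  if (!length(x$searched_databases)) fail("no searched databases.")
  extra <- setdiff(names(x$result_counts), x$searched_databases)
  if (length(extra)) {
    fail(sprintf("result_counts name unsearched database(s): %s",
                 paste(extra, collapse = ", ")))
  }
  if (any(x$result_counts < 0, na.rm = TRUE)) fail("negative result counts.")
  prov <- unique(unlist(x$includes$retrieved_by, use.names = FALSE))
  if (length(setdiff(prov, x$searched_databases))) {
    fail(sprintf("include provenance names unsearched database(s): %s",
                 paste(setdiff(prov, x$searched_databases), collapse = ", ")))
  }
  bad_year <- function(y) length(y) && any(!is.na(y) & (y < 1800 | y > 2100))
  if (bad_year(x$includes$year)) fail("include year outside 1800-2100.")
  if (anyDuplicated(x$includes$record_id)) fail("duplicated include record ids.")
  if (!is.null(x$records)) {
    if (anyDuplicated(x$records$record_id)) fail("duplicated record ids.")
    if (bad_year(x$records$year)) fail("record year outside 1800-2100.")
    if (length(setdiff(unique(x$records$database), x$searched_databases))) {
      fail("records attributed to unsearched database(s).")
    }
    got <- table(factor(x$records$database, levels = names(x$result_counts)))
    off <- names(x$result_counts)[as.integer(got) != x$result_counts]
    if (length(off)) {
      fail(sprintf("result_counts disagree with record tallies for: %s",
                   paste(off, collapse = ", ")))
    }
  }
  x
}

#' @export
print.review_dataset <- function(x, ...) {
  cat("<review_dataset> ", x$review_id, "\n",
      "  databases: ", paste(x$searched_databases, collapse = ", "), "\n",
      "  records:   ", if (is.null(x$records)) "counts only" else nrow(x$records), "\n",
      "  includes:  ", nrow(x$includes),
      " (", sum(lengths(x$includes$retrieved_by) == 0), " via other methods)\n", sep = "")
  invisible(x)
}

#' Construct a corpus of reviews
#'
#' @param reviews List of [review_dataset()] objects.
#' @param registry The [db_registry()] whose canonical tokens the reviews use.
#' @return A `corpus`.
#' @export
corpus <- function(reviews, registry = default_registry()) {
  stopifnot(is.list(reviews), inherits(registry, "db_registry"))
  ids <- vapply(reviews, function(r) r$review_id, character(1))
  if (anyDuplicated(ids)) {
    sr_abort("validation", sprintf("Duplicated review ids: %s",
                                   paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  used <- unique(unlist(lapply(reviews, function(r) r$searched_databases)))
  unknown <- setdiff(used, names(registry))
  if (length(unknown)) {
    sr_abort("validation", sprintf("Database(s) not in registry: %s",
                                   paste(unknown, collapse = ", ")))
  }
  structure(list(reviews = reviews, registry = registry), class = "corpus")
}

#' @export
print.corpus <- function(x, ...) {
  n_inc <- sum(vapply(x$reviews, function(r) nrow(r$includes), integer(1)))
  cat("<corpus> ", length(x$reviews), " reviews, ", n_inc, " included references, ",
      length(x$registry), " registered databases\n", sep = "")
  invisible(x)
}

corpus_review_ids <- function(x) vapply(x$reviews, function(r) r$review_id, character(1))

# reviews in which every member of combo was searched
evaluable_reviews <- function(corp, combo) {
  keep <- vapply(corp$reviews, function(r) all(combo %in% r$searched_databases), logical(1))
  corp$reviews[keep]
}
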