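#' Read a reference list (RIS or CSV)
#'
#' CSV files need the header columns `record_id`, `first_author_surname`,
#' `year`, `title`, `database` (optionally `second_author_surname`, and for
#' include lists `retrieved_by` with semicolon-joined canonical tokens).
#' RIS files carry no provenance, so the exporting database is given as an
#' argument. Database labels are canonicalized against the registry.
#'
#' @param path File path.
#' @param format `"ris"`, `"csv"`, or `"auto"` (by file extension).
#' @param database Provenance for RIS files (raw label, canonicalized here);
#'   overrides the `database` column of a CSV when supplied.
#' @param registry A [db_registry()].
#' @return A records tibble (see [reference-records]).
#' @export
read_reference_list <- function(path, format = c("auto", "ris", "csv"),
                                database = NULL, registry = default_registry()) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.ris$", path, ignore.case = TRUE)) "ris" else "csv"
  }
  if (format == "ris") {
    db <- if (is.null(database)) NA_character_ else canonicalize_database(database, registry)
    return(read_ris(path, database = db))
  }
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (nrow(df) == 0 && ncol(df) == 0) return(empty_records())
  need <- c("record_id", "first_author_surname", "year", "title")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    sr_abort("missing_field", sprintf("%s: CSV lacks column(s): %s", path,
                                      paste(missing, collapse = ", ")))
  }
  if (!is.null(database)) {
    df$database <- canonicalize_database(database, registry)
  } else if ("database" %in% names(df)) {
    ok <- !is.na(df$database) & nzchar(df$database)
    df$database[ok] <- canonicalize_database(df$database[ok], registry)
  } else {
    df$database <- NA_character_
  }
  if (anyNA(df$first_author_surname) & anyNA(df$title)) {
    both <- which(is.na(df$first_author_surname) & is.na(df$title))
    if (length(both)) {
      sr_abort("missing_field",
               sprintf("%s: row(s) %s have neither author nor title.",
                       path, paste(head(both, 5), collapse = ", ")))
    }
  }
  as_records(df)
}

#' Write a reference list (RIS or CSV)
#'
#' Inverse of [read_reference_list()]; round-trips surname, year, title and
#' provenance.
#'
#' @inheritParams read_reference_list
#' @param records A records tibble.
#' @export
write_reference_list <- function(records, path, format = c("auto", "ris", "csv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.ris$", path, ignore.case = TRUE)) "ris" else "csv"
  }
  if (format == "ris") return(write_ris(records, path))
  readr::write_csv(as_records(records), path, progress = FALSE)
  invisible(path)
}

#' Load a corpus from a manifest
#'
#' The manifest is a YAML (or JSON) file listing each review's searched
#' databases, metadata, and either per-database result counts or the files
#' holding its record-level exports and include list. File paths are
#' resolved relative to the manifest. All review invariants are enforced;
#' violations raise a validation error naming the review.
#'
#' ```yaml
#' reviews:
#' - review_id: R01
#'   searched_databases: [EMBASE, MEDLINE]
#'   metadata: {domain: therapy}
#'   records:
#'   - {path: R01_embase.csv, database: EMBASE}
#'   includes: {path: R01_includes.csv}
#' ```
#'
#' @param config_path Manifest path.
#' @param registry A [db_registry()].
#' @return A [corpus()].
#' @export
load_corpus <- function(config_path, registry = default_registry()) {
  man <- yaml::read_yaml(config_path)
  if (is.null(man$reviews)) {
    sr_abort("validation", sprintf("%s: manifest has no 'reviews' entry.", config_path))
  }
  base <- dirname(config_path)
  reviews <- lapply(man$reviews, function(rv) {
    id <- rv$review_id %||% sr_abort("validation", "A review entry lacks review_id.")
    searched <- canonicalize_database(unlist(rv$searched_databases), registry)
    records <- NULL
    if (!is.null(rv$records)) {
      parts <- lapply(rv$records, function(f) {
        read_reference_list(file.path(base, f$path), format = f$format %||% "auto",
                            database = f$database, registry = registry)
      })
      records <- dplyr::bind_rows(parts)
    }
    includes <- if (!is.null(rv$includes)) {
      f <- rv$includes
      p <- file.path(base, f$path)
      fmt <- f$format %||% (if (grepl("\\.ris$", p, ignore.case = TRUE)) "ris" else "csv")
      inc <- if (fmt == "ris") {
        as_includes(read_ris(p))
      } else {
        as_includes(readr::read_csv(p, show_col_types = FALSE, progress = FALSE))
      }
      inc$retrieved_by <- lapply(inc$retrieved_by, function(x) {
        if (length(x)) canonicalize_database(x, registry) else character()
      })
      inc
    } else empty_includes()
    rc <- if (!is.null(rv$result_counts)) unlist(rv$result_counts) else NULL
    if (!is.null(rc)) names(rc) <- canonicalize_database(names(rc), registry)
    review_dataset(id, searched, includes, records = records,
                   result_counts = rc, metadata = rv$metadata %||% list())
  })
  corpus(reviews, registry)
}

#' Write a corpus to a directory as manifest + CSV files
#'
#' Emits one records CSV and one includes CSV per review plus a
#' `manifest.yaml`, such that [load_corpus()] on the manifest reproduces the
#' corpus.
#'
#' @param corp A [corpus()].
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_corpus <- function(corp, dir) {
  stopifnot(inherits(corp, "corpus"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  entries <- lapply(corp$reviews, function(rv) {
    ent <- list(review_id = rv$review_id,
                searched_databases = as.list(rv$searched_databases),
                metadata = rv$metadata)
    ent$result_counts <- as.list(rv$result_counts)
    if (!is.null(rv$records)) {
      fn <- sprintf("%s_records.csv", rv$review_id)
      readr::write_csv(as_records(rv$records), file.path(dir, fn), progress = FALSE)
      ent$records <- list(list(path = fn, format = "csv"))
    }
    fn_inc <- sprintf("%s_includes.csv", rv$review_id)
    inc <- rv$includes
    flat <- inc
    flat$retrieved_by <- vapply(inc$retrieved_by, paste, character(1), collapse = ";")
    readr::write_csv(flat, file.path(dir, fn_inc), progress = FALSE)
    ent$includes <- list(path = fn_inc, format = "csv")
    ent
  })
  manifest <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(list(reviews = entries), manifest)
  invisible(manifest)
}
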