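# Minimal RIS reader/writer. RIS is the tagged line format reference
# managers use for export ("TY  - JOUR", "AU  - Smith, J.", ..., "ER  - ").
# Only the tags the pipeline needs are interpreted: AU (authors, surname
# before the comma), PY/Y1 (year), TI/T1 (title), ID (record id). Unknown
# tags are carried over unharmed by the reader and simply ignored.

ris_tag_re <- "^([A-Z][A-Z0-9])  - ?(.*)$"

#' Read a RIS file into a reference-record table
#'
#' @param path RIS file path.
#' @param database Canonical token of the database the file was exported
#'   from (RIS has no provenance tag; the exporting database is sidecar
#'   knowledge).
#' @return A records tibble (see [reference-records]); `second_author_surname`
#'   is the second `AU` entry when present.
#' @export
read_ris <- function(path, database = NA_character_) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  recs <- list()
  cur <- NULL
  open_at <- NA_integer_
  flush <- function(cur, lineno) {
    au <- cur$AU
    if (is.null(au) && is.null(cur$TI)) {
      sr_abort("missing_field",
               sprintf("%s: record ending at line %d has neither author nor title.",
                       path, lineno))
    }
    surname <- function(a) trimws(strsplit(a, ",", fixed = TRUE)[[1]][1])
    tibble(
      record_id = cur$ID %||% NA_character_,
      first_author_surname = if (length(au) >= 1) surname(au[[1]]) else NA_character_,
      second_author_surname = if (length(au) >= 2) surname(au[[2]]) else NA_character_,
      year = suppressWarnings(as.integer(substr(cur$PY %||% NA_character_, 1, 4))),
      title = cur$TI %||% NA_character_,
      database = database
    )
  }
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    if (!nzchar(trimws(ln))) next
    m <- regmatches(ln, regexec(ris_tag_re, ln))[[1]]
    if (length(m) == 0) {
      if (is.null(cur)) {
        sr_abort("parse", sprintf("%s: line %d is not a RIS tag line: %s",
                                  path, i, sQuote(ln)))
      }
      next  # continuation line of a long field; not needed for matching
    }
    tag <- m[[2]]; val <- m[[3]]
    if (tag == "TY") {
      if (!is.null(cur)) {
        sr_abort("parse", sprintf("%s: line %d starts a record before 'ER' closed the one at line %d.",
                                  path, i, open_at))
      }
      cur <- list(); open_at <- i
    } else if (tag == "ER") {
      if (is.null(cur)) {
        sr_abort("parse", sprintf("%s: stray 'ER' at line %d.", path, i))
      }
      recs[[length(recs) + 1L]] <- flush(cur, i)
      cur <- NULL
    } else if (!is.null(cur)) {
      if (tag == "AU") cur$AU <- c(cur$AU, val)
      else if (tag %in% c("PY", "Y1") && is.null(cur$PY)) cur$PY <- val
      else if (tag %in% c("TI", "T1") && is.null(cur$TI)) cur$TI <- val
      else if (tag == "ID") cur$ID <- val
    }
  }
  if (!is.null(cur)) {
    sr_abort("parse", sprintf("%s: record opened at line %d never closed with 'ER'.",
                              path, open_at))
  }
  out <- if (length(recs)) dplyr::bind_rows(recs) else empty_records()
  if (anyNA(out$record_id) && nrow(out)) {
    out$record_id <- ifelse(is.na(out$record_id),
                            sprintf("%s-%04d", basename(path), seq_len(nrow(out))),
                            out$record_id)
  }
  as_records(out)
}

#' Write a reference-record table as RIS
#'
#' @param records A records tibble.
#' @param path Output path.
#' @export
write_ris <- function(records, path) {
  records <- as_records(records)
  fmt1 <- function(r) {
    au2 <- if (!is.na(r$second_author_surname))
      sprintf("AU  - %s", r$second_author_surname) else NULL
    c("TY  - JOUR",
      sprintf("ID  - %s", r$record_id),
      if (!is.na(r$first_author_surname)) sprintf("AU  - %s", r$first_author_surname),
      au2,
      if (!is.na(r$year)) sprintf("PY  - %d", r$year),
      if (!is.na(r$title)) sprintf("TI  - %s", r$title),
      "ER  - ", "")
  }
  lines <- unlist(lapply(seq_len(nrow(records)), function(i) fmt1(records[i, ])))
  writeLines(lines %||% character(), path, useBytes = TRUE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
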