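#' Text normalization for bibliographic identity
#'
#' Case-folds, strips diacritics (via ICU Latin-ASCII transliteration),
#' drops punctuation and collapses whitespace. Used for author surnames and
#' title tokens so that the same work exported by different databases
#' compares equal despite cosmetic differences.
#'
#' @param x Character vector.
#' @return Normalized character vector.
#' @export
normalize_text <- function(x) {
  x <- stringi::stri_trans_general(as.character(x), "Latin-ASCII")
  x <- tolower(x)
  x <- gsub("[^a-z0-9 ]+", " ", x)
  trimws(gsub("[[:space:]]+", " ", x))
}

title_tokens <- function(x) {
  toks <- strsplit(normalize_text(x), " ", fixed = TRUE)
  lapply(toks, function(t) unique(t[nzchar(t)]))
}

title_jaccard <- function(a, b) {
  ta <- title_tokens(a)[[1]]; tb <- title_tokens(b)[[1]]
  if (!length(ta) && !length(tb)) return(1)
  if (!length(ta) || !length(tb)) return(0)
  length(intersect(ta, tb)) / length(union(ta, tb))
}

key_sentinel <- "\x01no-author"  # control-char prefix: cannot collide with a surname

#' Build the author-year match key
#'
#' Locating an included reference in the combined library starts from the
#' first author's surname and the publication year, the same probe a
#' searcher types into a reference manager. The key is the normalized
#' `"surname|year"` token. When the surname is missing a sentinel key is
#' returned, which forces title-stage matching.
#'
#' @param surname First-author surname(s).
#' @param year Publication year(s).
#' @return Character vector of keys.
#' @examples
#' build_match_key("Smith", 2015)        # "smith|2015"
#' build_match_key("  SMÍTH ", 2015)  # "smith|2015"
#' @export
build_match_key <- function(surname, year) {
  s <- gsub(" ", "", normalize_text(surname))
  s[is.na(surname) | !nzchar(s)] <- key_sentinel
  paste0(s, "|", ifelse(is.na(year), "", as.character(as.integer(year))))
}

# distinct-work grouping inside one surname|year candidate set: records whose
# normalized titles are identical are the same work seen through different
# databases.
work_signature <- function(records) {
  paste(gsub(" ", "", normalize_text(records$first_author_surname)),
        records$year, normalize_text(records$title), sep = "|")
}

#' Match one included reference against a review library
#'
#' Stage 1 selects library records sharing the `surname|year` key. When
#' those records span more than one distinct work, stage 2b (optional)
#' keeps works whose second-author surname equals the include's, and stage
#' 2 filters by title-token Jaccard similarity at `title_threshold`. All
#' records of the surviving work -- one per retrieving database --
#' contribute provenance. Zero survivors mean the include was found by
#' other search methods (`status = "unmatched"`); more than one surviving
#' work is never silently chosen (`"ambiguous-unresolved"`, excluded
#' downstream).
#'
#' @param included One-row includes tibble.
#' @param library Records tibble (the review's combined exports).
#' @param title_threshold Jaccard similarity cut-off in (0, 1\]; default 0.6.
#' @return One-row tibble: `include_id`, `status` (matched, unmatched,
#'   ambiguous-resolved, ambiguous-unresolved), `matched_record_ids` and
#'   `provenance` (list-columns).
#' @export
match_included <- function(included, library, title_threshold = 0.6) {
  stopifnot(title_threshold > 0, title_threshold <= 1)
  res <- function(status, rows) {
    tibble(include_id = included$record_id, status = status,
           matched_record_ids = list(rows$record_id),
           provenance = list(sort(unique(rows$database[!is.na(rows$database)]))))
  }
  none <- library[0, ]
  key <- build_match_key(included$first_author_surname, included$year)
  lib_keys <- build_match_key(library$first_author_surname, library$year)
  cand <- if (startsWith(key, key_sentinel)) {
    if (is.na(included$year)) library
    else library[!is.na(library$year) & library$year == included$year, , drop = FALSE]
  } else {
    library[lib_keys == key, , drop = FALSE]
  }
  if (nrow(cand) == 0) return(res("unmatched", none))

  sig <- work_signature(cand)
  works <- unique(sig)
  force_title <- startsWith(key, key_sentinel)
  if (length(works) == 1 && !force_title) return(res("matched", cand))

  resolved <- FALSE
  # stage 2b: exact second-author agreement, when both sides carry one
  if (!force_title && !is.na(included$second_author_surname)) {
    s2 <- gsub(" ", "", normalize_text(included$second_author_surname))
    cand_s2 <- gsub(" ", "", normalize_text(cand$second_author_surname))
    keep_sig <- unique(sig[!is.na(cand$second_author_surname) & cand_s2 == s2])
    if (length(keep_sig) == 1) {
      return(res("ambiguous-resolved", cand[sig == keep_sig, , drop = FALSE]))
    }
    if (length(keep_sig) > 1) {
      cand <- cand[sig %in% keep_sig, , drop = FALSE]
      sig <- sig[sig %in% keep_sig]
      works <- keep_sig
      resolved <- TRUE
    } # zero second-author survivors: fall through to title similarity on all
  }
  # stage 2: title-token Jaccard against each distinct work
  if (is.na(included$title)) return(res("ambiguous-unresolved", none))
  first_of <- match(works, sig)
  sims <- vapply(first_of, function(i) title_jaccard(included$title, cand$title[i]),
                 numeric(1))
  surv <- works[sims >= title_threshold]
  if (length(surv) == 0) return(res("unmatched", none))
  if (length(surv) > 1) return(res("ambiguous-unresolved", none))
  status <- if (force_title && length(works) == 1 && !resolved) "matched" else "ambiguous-resolved"
  res(status, cand[sig == surv, , drop = FALSE])
}

#' Match every included reference of a review
#'
#' @param review A [review_dataset()] whose `records` hold the combined
#'   multi-database library.
#' @inheritParams match_included
#' @return Tibble of match results, one row per include.
#' @export
match_review <- function(review, title_threshold = 0.6) {
  if (is.null(review$records)) {
    sr_abort("validation", sprintf("Review %s has no record-level library to match against.",
                                   sQuote(review$review_id)))
  }
  inc <- review$includes
  dplyr::bind_rows(lapply(seq_len(nrow(inc)), function(i) {
    match_included(inc[i, ], review$records, title_threshold)
  }))
}

#' Attach matched provenance to a review's includes
#'
#' Overwrites each include's `retrieved_by` with the provenance of its
#' match result. Unmatched and ambiguous-unresolved includes get empty
#' provenance; they are attributed to other search methods and drop out of
#' retrieved-basis recall denominators. A summary of match statuses is
#' stored in `review$match_summary`; unresolved ambiguity triggers a
#' warning rather than a silent choice.
#'
#' @param review A [review_dataset()].
#' @param results Match results from [match_review()], one row per include.
#' @return The updated `review_dataset`.
#' @export
attach_provenance <- function(review, results) {
  inc <- review$includes
  if (nrow(results) != nrow(inc) || !setequal(results$include_id, inc$record_id)) {
    sr_abort("consistency", sprintf("Review %s: match results do not cover the includes one-to-one.",
                                    sQuote(review$review_id)))
  }
  known <- if (is.null(review$records)) character() else review$records$record_id
  stray <- setdiff(unlist(results$matched_record_ids, use.names = FALSE), known)
  if (length(stray)) {
    sr_abort("consistency",
             sprintf("Review %s: matched record id(s) absent from the library: %s",
                     sQuote(review$review_id), paste(head(stray, 5), collapse = ", ")))
  }
  ord <- match(inc$record_id, results$include_id)
  inc$retrieved_by <- results$provenance[ord]
  review$includes <- inc
  review$match_summary <- as.data.frame(table(status = results$status),
                                        responseName = "n")
  n_unres <- sum(results$status == "ambiguous-unresolved")
  if (n_unres > 0) {
    warn(sprintf("Review %s: %d include(s) remain ambiguous-unresolved and are excluded from analysis.",
                 review$review_id, n_unres))
  }
  validate_review_dataset(review)
}
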