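#' Search performance measures
#'
#' The three standard measures of literature-search performance:
#'
#' * **recall** -- included references retrieved by the database(s) under
#'   evaluation, divided by the included references retrieved by all
#'   searched databases combined (the retrieved-includes denominator).
#' * **precision** -- included references retrieved divided by the total
#'   (deduplicated) records the database(s) retrieved.
#' * **number needed to read (NNR)** -- records retrieved per included
#'   reference found; the reciprocal of precision.
#'
#' All three return full-precision fractions; rounding belongs to
#' reporting ([format_pct()], [report_performance()]).
#'
#' @param includes_retrieved Included references retrieved by the
#'   combination under evaluation.
#' @param includes_total Included references retrieved by all searched
#'   databases (recall denominator).
#' @param results_total Deduplicated records retrieved by the combination.
#' @return Numeric vector.
#' @examples
#' recall(1716, 1746)                      # 0.9828...
#' precision(1716, 125257)                 # 0.0137...
#' number_needed_to_read(125257, 1716)     # 72.99...
#' @name performance-measures
NULL

#' @rdname performance-measures
#' @export
recall <- function(includes_retrieved, includes_total) {
  check_positive_denominator(includes_total, "includes_total")
  stopifnot(all(includes_retrieved >= 0), all(includes_retrieved <= includes_total))
  includes_retrieved / includes_total
}

#' @rdname performance-measures
#' @export
precision <- function(includes_retrieved, results_total) {
  check_positive_denominator(results_total, "results_total")
  stopifnot(all(includes_retrieved >= 0), all(includes_retrieved <= results_total))
  includes_retrieved / results_total
}

#' @rdname performance-measures
#' @export
number_needed_to_read <- function(results_total, includes_retrieved) {
  check_positive_denominator(includes_retrieved, "includes_retrieved")
  results_total / includes_retrieved
}

include_provenance_hits <- function(review, combo) {
  vapply(review$includes$retrieved_by, function(p) length(intersect(p, combo)) > 0,
         logical(1))
}

#' Recall of a database combination within one review
#'
#' The numerator counts includes whose provenance intersects the
#' combination. Two denominators are in use: `basis = "retrieved"` (the
#' default) counts only includes retrieved by at least one searched
#' database, so the full searched set always scores recall 1; `basis =
#' "published"` counts every include of the published review, including
#' those found by other search methods, and is therefore never larger.
#'
#' @param review A [review_dataset()] with provenance attached.
#' @param combo Character vector of canonical database tokens.
#' @param basis `"retrieved"` or `"published"`.
#' @return A fraction.
#' @export
review_recall <- function(review, combo, basis = c("retrieved", "published")) {
  basis <- match.arg(basis)
  combo <- unique(as.character(combo))
  if (!all(combo %in% review$searched_databases)) {
    sr_abort("combination_not_searched",
             sprintf("Review %s did not search: %s", sQuote(review$review_id),
                     paste(setdiff(combo, review$searched_databases), collapse = ", ")))
  }
  retrieved_any <- lengths(review$includes$retrieved_by) > 0
  denom <- if (basis == "retrieved") sum(retrieved_any) else nrow(review$includes)
  check_positive_denominator(denom, sprintf("review %s include count (basis %s)",
                                            review$review_id, basis))
  sum(include_provenance_hits(review, combo)) / denom
}
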