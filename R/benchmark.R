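#' Benchmark study summary tables
#'
#' Aggregate counts from a prospective benchmark of 58 biomedical
#' systematic reviews whose searches were documented at search time by a
#' single academic medical library. The reviews included 1830 references
#' in total; 1746 of them were retrieved by at least one database search
#' (the retrieved-includes recall denominator) and 84 were found by other
#' methods (hand searching, reference checking, expert contact). These
#' tables are the package's built-in worked example, and the synthetic
#' generator's default calibration targets are taken from them.
#'
#' * `benchmark_unique_contributions()` — per-database unique included
#'   references (provenance of exactly one database).
#' * `benchmark_performance_counts()` — deduplicated result counts and
#'   includes retrieved for the four key databases (Embase, MEDLINE, Web of
#'   Science, Google Scholar) and all their combinations; feeding these
#'   counts through [recall()], [precision()] and [number_needed_to_read()]
#'   reproduces the benchmark's printed performance table.
#' * `benchmark_practice_sample()` — how often each key-database
#'   combination was searched in an independent sample of 200 recently
#'   published systematic reviews (198 searched at least one key database).
#' * `benchmark_recall_probabilities()` — the benchmark's measured
#'   probabilities that each combination reaches 95% and 100% recall,
#'   as printed (whole percents).
#'
#' @return Tibbles; see details.
#' @name benchmark
NULL

#' @rdname benchmark
#' @export
benchmark_unique_contributions <- function() {
  tibble(
    database = c("EMBASE", "MEDLINE", "WOS", "GS", "CINAHL", "SCOPUS",
                 "PSYCINFO", "SPORTDISCUS"),
    n_reviews_used = c(58L, 58L, 58L, 58L, 18L, 24L, 11L, 2L),
    n_reviews_with_unique = c(29L, 27L, 19L, 24L, 1L, 3L, 1L, 2L),
    n_unique_refs = c(132L, 69L, 37L, 37L, 6L, 5L, 2L, 3L)
  )
}

#' @rdname benchmark
#' @export
benchmark_performance_counts <- function() {
  out <- tibble(
    combo_key = c("EMBASE", "MEDLINE", "WOS", "GS",
                  "EMBASE+MEDLINE", "EMBASE+WOS", "EMBASE+GS",
                  "MEDLINE+WOS", "GS+MEDLINE", "GS+WOS",
                  "EMBASE+GS+MEDLINE", "EMBASE+MEDLINE+WOS",
                  "EMBASE+GS+WOS", "GS+MEDLINE+WOS",
                  "EMBASE+GS+MEDLINE+WOS"),
    results_total = c(85521L, 56340L, 48561L, 10342L,
                      100444L, 104444L, 91411L,
                      75263L, 62230L, 54451L,
                      106334L, 119367L, 110334L, 81153L,
                      125257L),
    includes_retrieved = c(1500L, 1375L, 1189L, 601L,
                           1621L, 1585L, 1570L,
                           1481L, 1459L, 1320L,
                           1674L, 1674L, 1638L, 1528L,
                           1716L)
  )
  attr(out, "includes_total") <- 1746L
  attr(out, "includes_published") <- 1830L
  out
}

#' @rdname benchmark
#' @export
benchmark_practice_sample <- function() {
  practice_sample(
    combos = list(
      c("EMBASE", "MEDLINE"),
      "MEDLINE",
      c("EMBASE", "MEDLINE", "WOS"),
      c("MEDLINE", "WOS"),
      c("GS", "MEDLINE"),
      c("GS", "MEDLINE", "WOS"),
      c("EMBASE", "GS", "MEDLINE"),
      "EMBASE",
      c("EMBASE", "WOS"),
      "WOS"
    ),
    frequency = c(73L, 41L, 40L, 21L, 7L, 7L, 5L, 2L, 1L, 1L),
    n_total = 200L
  )
}

#' @rdname benchmark
#' @export
benchmark_recall_probabilities <- function() {
  keys <- benchmark_practice_sample()$combo_key
  tibble(
    combo_key = rep(keys, 2),
    threshold = rep(c(0.95, 1), each = length(keys)),
    probability = c(
      c(47, 16, 64, 21, 26, 37, 76, 19, 40, 7) / 100,
      c(24,  9, 36, 16, 16, 29, 41, 14, 28, 7) / 100
    )
  )
}
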