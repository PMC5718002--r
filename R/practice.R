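#' Practice sample of database combinations
#'
#' A frequency table of which database combinations a sample of published
#' systematic reviews reported searching, after reduction to the key
#' database set. Entries whose combination is empty (reviews that searched
#' none of the key databases) count toward the sample total but can never
#' reach the recall target.
#'
#' @param combos List of character vectors (canonical tokens), or a
#'   character vector of `+`-joined keys.
#' @param frequency Non-negative integer counts, same length.
#' @param n_total Sample size including reviews matching no key database;
#'   defaults to `sum(frequency)`.
#' @return A `practice_sample` tibble with attribute `n_total`.
#' @export
practice_sample <- function(combos, frequency, n_total = sum(frequency)) {
  if (is.character(combos)) combos <- strsplit(combos, "+", fixed = TRUE)
  stopifnot(length(combos) == length(frequency), all(frequency >= 0))
  if (sum(frequency) > n_total) {
    sr_abort("validation", "Sum of frequencies exceeds the sample total.")
  }
  out <- tibble(combo = lapply(combos, function(x) sort(unique(as.character(x)))),
                combo_key = vapply(combos, combo_key, character(1)),
                frequency = as.integer(frequency))
  attr(out, "n_total") <- as.integer(n_total)
  class(out) <- c("practice_sample", class(out))
  out
}

#' Reduce a searched set to the key databases
#'
#' Published reviews search many databases; for the probability model only
#' the intersection with the key set (the candidates whose performance is
#' known) matters. An empty intersection is allowed and contributes zero
#' probability.
#'
#' @param searched Character vector of canonical tokens.
#' @param key_set Non-empty character vector of key databases.
#' @return Sorted character vector (possibly empty).
#' @export
reduce_to_key_combo <- function(searched, key_set) {
  stopifnot(length(key_set) >= 1)
  sort(intersect(unique(as.character(searched)), key_set))
}

#' Derive combination recall probabilities from a corpus
#'
#' For every non-empty subset of the key set and every threshold, the
#' probability that the combination reaches the threshold is estimated as
#' its attainment share over the corpus (the share of reviews in which the
#' combination's recall reached the threshold).
#'
#' @inheritParams evaluate_combination
#' @param key_set Character vector of key databases.
#' @param thresholds Recall thresholds, conventionally `c(1, 0.95)`.
#' @param comparator Passed to [attainment()].
#' @return Tibble: `combo_key`, `threshold`, `probability`.
#' @export
derive_probability_table <- function(corp, key_set, thresholds = c(1, 0.95),
                                     comparator = c(">=", ">")) {
  comparator <- match.arg(comparator)
  key_set <- sort(unique(as.character(key_set)))
  rows <- lapply(all_subsets(key_set), function(s) {
    at <- attainment(corp, s, thresholds = thresholds, comparator = comparator)
    tibble(combo_key = at$combo_key, threshold = at$threshold, probability = at$share)
  })
  dplyr::bind_rows(rows)
}

#' Probability that a practice sample reached acceptable recall
#'
#' Weighted average, over the sampled reviews, of the probability that the
#' combination each review searched reaches the recall threshold:
#' `sum(frequency/denominator * P(combo reaches threshold))`. Reviews whose
#' combination matches no key database contribute probability zero.
#'
#' The conventional denominator (`"matched"`) is the sum of frequencies of
#' reviews that searched at least one key database, matching how such
#' frequency tables print their total; `"total"` divides by the full
#' sample size instead.
#'
#' @param sample A [practice_sample()].
#' @param probs Probability table ([derive_probability_table()] or printed
#'   values): columns `combo_key`, `threshold`, `probability`.
#' @param threshold The recall threshold to look up.
#' @param denominator `"matched"` or `"total"`.
#' @return A fraction in \[0, 1\].
#' @export
probability_of_acceptable_recall <- function(sample, probs, threshold,
                                             denominator = c("matched", "total")) {
  denominator <- match.arg(denominator)
  pr <- probs[abs(probs$threshold - threshold) < 1e-9, , drop = FALSE]
  if (!nrow(pr)) {
    sr_abort("missing_probability",
             sprintf("No probabilities at threshold %s.", format(threshold)))
  }
  nonempty <- nzchar(sample$combo_key)
  missing <- setdiff(sample$combo_key[nonempty], pr$combo_key)
  if (length(missing)) {
    sr_abort("missing_probability",
             sprintf("No recall probability for combination(s): %s",
                     paste(missing, collapse = "; ")))
  }
  p <- ifelse(nonempty, pr$probability[match(sample$combo_key, pr$combo_key)], 0)
  denom <- if (denominator == "matched") sum(sample$frequency[nonempty])
           else attr(sample, "n_total")
  check_positive_denominator(denom, "practice sample size")
  sum(sample$frequency * p) / denom
}
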