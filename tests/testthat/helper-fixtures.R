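# Shared fixture builders. Toy corpora use a three-database registry so the
# hand-enumerable examples stay small; synthetic corpora come from the
# package generator, with the irrelevant-record pool scaled down where only
# exact recount equality (not realistic screening volume) is under test.

toy_registry <- function() {
  db_registry(list(A = "a db", B = "b db", C = "c db"))
}

# provenance: list of character vectors, one per include
toy_review <- function(id, searched, provenance, result_counts = NULL,
                       metadata = list()) {
  n <- length(provenance)
  includes <- tibble::tibble(
    record_id = sprintf("%s-I%02d", id, seq_len(n)),
    first_author_surname = sprintf("Author%02d", seq_len(n)),
    second_author_surname = NA_character_,
    year = 2000L + seq_len(n) %% 20,
    title = sprintf("study number %d of review %s", seq_len(n), id),
    retrieved_by = provenance,
    is_included = TRUE
  )
  if (is.null(result_counts)) {
    result_counts <- stats::setNames(rep(100L, length(searched)), searched)
  }
  review_dataset(id, searched, includes, result_counts = result_counts,
                 metadata = metadata)
}

toy_corpus <- function(reviews) corpus(reviews, toy_registry())

# a review whose recall for combo {A} is exactly `frac`
toy_review_with_recall <- function(id, frac, denom = 20) {
  hits <- round(frac * denom)
  prov <- c(replicate(hits, "A", simplify = FALSE),
            replicate(denom - hits, "B", simplify = FALSE))
  toy_review(id, c("A", "B"), prov)
}

# generator configuration with the screening-volume pool scaled down; the
# membership model (the part oracle equality exercises) is untouched
small_synth_config <- function(seed, n_reviews = 58, ...) {
  base_rates <- c(EMBASE = 1475, MEDLINE = 971, WOS = 837, GS = 650,
                  COCHRANE_CENTRAL = 300, SCOPUS = 800)
  synthetic_config(
    n_reviews = n_reviews,
    noise_volume = list(pool_mean = 150, pool_size = 8,
                        rates = base_rates * 150 / 2500),
    gs_rank_cap = 30, gs_low_cap = 15,
    seed = seed,
    ...
  )
}

key_dbs <- c("EMBASE", "GS", "MEDLINE", "WOS")

# naive per-review full-search statistics (each review's own searched set)
oracle_full_stats <- function(truth) {
  rows <- lapply(truth$reviews, function(tr) {
    inc_any <- rowSums(tr$inc_mat) > 0
    tibble::tibble(review_id = tr$review_id,
                   results_total = sum(rowSums(tr$noise_mat) > 0) + sum(inc_any),
                   includes_retrieved = sum(inc_any))
  })
  dplyr::bind_rows(rows)
}

# naive per-include recount of unique contributions from the truth ledger
oracle_unique_counts <- function(truth) {
  dbs <- truth$config$databases
  out <- stats::setNames(rep(0L, length(dbs)), dbs)
  for (tr in truth$reviews) {
    for (i in seq_len(nrow(tr$inc_mat))) {
      hit <- colnames(tr$inc_mat)[tr$inc_mat[i, ]]
      if (length(hit) == 1) out[[hit]] <- out[[hit]] + 1L
    }
  }
  out
}
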