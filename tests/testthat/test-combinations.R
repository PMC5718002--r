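test_that("unique contributions count single-provenance includes", {
  corp <- toy_corpus(list(
    toy_review("R1", c("A", "B"), list("A", c("A", "B"), "B", "B"))))
  uc <- unique_contributions(corp)
  expect_equal(uc$n_unique_refs[uc$database == "A"], 1)
  expect_equal(uc$n_unique_refs[uc$database == "B"], 2)
  expect_equal(attr(uc, "n_unique_total"), 3)

  all_multi <- toy_corpus(list(
    toy_review("R2", c("A", "B"), list(c("A", "B"), c("A", "B")))))
  expect_true(all(unique_contributions(all_multi)$n_unique_refs == 0))
})

test_that("unique totals are conserved against the ledger", {
  g <- generate_corpus(small_synth_config(seed = 41))
  uc <- unique_contributions(g$corpus)
  oracle <- oracle_unique_counts(g$truth)
  expect_equal(setNames(uc$n_unique_refs, uc$database)[names(oracle)], oracle)
  expect_equal(attr(uc, "n_unique_total"), sum(oracle))
  prov_len <- unlist(lapply(g$corpus$reviews,
                            function(r) lengths(r$includes$retrieved_by)))
  expect_equal(sum(uc$n_unique_refs), sum(prov_len == 1))
})

test_that("candidate selection orders by unique contribution with stable ties", {
  cand <- select_candidates(benchmark_unique_contributions(), 4)
  expect_equal(cand[1:2], c("EMBASE", "MEDLINE"))
  # WOS and GS tie at 37 unique refs; GS contributed to more reviews
  expect_setequal(cand[3:4], c("WOS", "GS"))
  expect_equal(cand[3], "GS")

  set.seed(42)
  tbl <- tibble::tibble(database = sprintf("D%02d", 1:8),
                        n_reviews_used = 50L,
                        n_reviews_with_unique = sample(0:20, 8, TRUE),
                        n_unique_refs = sample(0:50, 8, TRUE))
  ord <- with(tbl, order(-n_unique_refs, -n_reviews_with_unique, database))
  expect_equal(select_candidates(tbl, 8), tbl$database[ord])
})

test_that("single-review evaluation has the boundary values", {
  corp <- toy_corpus(list(toy_review("R1", c("A", "B"),
                                     list("A", c("A", "B"), "B"))))
  perf <- evaluate_combination(corp, c("A", "B"))
  expect_equal(perf$overall_recall, 1)
  expect_equal(perf$median_recall, 1)
  expect_equal(perf$min_recall, 1)
  expect_equal(perf$pct_full_recall, 1)
  expect_error(evaluate_combination(corp, "C"),
               class = "searchrecall_no_evaluable_review")
})

test_that("subset enumeration is complete, ordered, and self-consistent", {
  g <- generate_corpus(small_synth_config(seed = 43, n_reviews = 10))
  perf <- evaluate_all_subsets(g$corpus, key_dbs)
  expect_equal(nrow(perf), 15)
  sizes <- lengths(perf$combo)
  expect_true(all(diff(sizes) >= 0))
  for (i in sample(nrow(perf), 5)) {
    single <- evaluate_combination(g$corpus, perf$combo[[i]])
    expect_equal(perf[i, -1], single[, -1])
  }
  expect_error(evaluate_all_subsets(g$corpus, sprintf("D%02d", 1:13)),
               class = "searchrecall_too_many_candidates")
})

test_that("attainment counts reviews at or above each threshold", {
  corp <- toy_corpus(list(
    toy_review_with_recall("R1", 1.0),
    toy_review_with_recall("R2", 0.96, denom = 25),
    toy_review_with_recall("R3", 0.90, denom = 20),
    toy_review_with_recall("R4", 0.50, denom = 20)))
  at <- attainment(corp, "A")
  expect_equal(at$share[at$threshold == 0.95], 0.5)
  expect_equal(at$share[at$threshold == 0.90], 0.75)
  expect_true(all(diff(at$share) >= 0))   # thresholds descend, shares rise
  # threshold 1 equals the percentage-100%-recall column
  perf <- evaluate_combination(corp, "A")
  expect_equal(at$share[at$threshold == 1], perf$pct_full_recall)
  # strict comparator drops the review sitting exactly on 0.90
  at_strict <- attainment(corp, "A", comparator = ">")
  expect_equal(at_strict$share[at_strict$threshold == 0.90], 0.5)
})

test_that("stratified attainment reduces to the plain version for one group", {
  g <- generate_corpus(small_synth_config(seed = 44, n_reviews = 10,
                                          domain_probs = c(therapy = 1)))
  plain <- attainment(g$corpus, c("EMBASE", "MEDLINE"))
  strat <- stratified_attainment(g$corpus, c("EMBASE", "MEDLINE"), "domain")
  expect_equal(unique(strat$group), "therapy")
  expect_equal(strat$share, plain$share)
})

test_that("a planted domain effect is recovered in the right order", {
  cfg <- small_synth_config(seed = 45, n_reviews = 40,
                            domain_probs = c(therapy = 0.5, prognosis = 0.5),
                            domain_shift = c(therapy = 1.2, prognosis = -1.2))
  g <- generate_corpus(cfg)
  strat <- stratified_attainment(g$corpus, c("EMBASE", "MEDLINE"), "domain",
                                 thresholds = 0.9)
  expect_gt(strat$share[strat$group == "therapy"],
            strat$share[strat$group == "prognosis"])
})

test_that("ratio operations have their boundary values and match the ledger", {
  g <- generate_corpus(small_synth_config(seed = 46, n_reviews = 6))
  full_oracle <- oracle_full_stats(g$truth)
  for (i in seq_along(g$corpus$reviews)) {
    rv <- g$corpus$reviews[[i]]
    expect_equal(results_reduction_ratio(rv, rv$searched_databases), 1)
    expect_equal(precision_improvement_ratio(rv, rv$searched_databases), 1)
  }
  combo <- c("EMBASE", "MEDLINE")
  oracle <- truth_recount(g$truth, combo)
  red <- corpus_ratios(g$corpus, combo, "reduction")
  ids <- oracle$per_review$review_id
  full_res <- setNames(full_oracle$results_total, full_oracle$review_id)
  full_prec <- setNames(full_oracle$includes_retrieved / full_oracle$results_total,
                        full_oracle$review_id)
  expect_equal(red$ratio,
               oracle$per_review$results_total / full_res[ids],
               ignore_attr = TRUE)
  pr <- corpus_ratios(g$corpus, combo, "precision")
  oracle_prec <- oracle$per_review$includes_retrieved / oracle$per_review$results_total
  expect_equal(pr$ratio, oracle_prec / full_prec[ids],
               ignore_attr = TRUE)
})

test_that("greedy cover picks minimal obvious sets and respects enumeration", {
  # one database reaching the target alone -> singleton
  corp <- toy_corpus(list(
    toy_review("R1", c("A", "B"), list("A", "A", c("A", "B"))),
    toy_review("R2", c("A", "B"), list("A", c("A", "B")))))
  expect_equal(greedy_cover(corp, 1, 1), "A")

  # only the full set reaches 100% recall everywhere
  corp2 <- toy_corpus(list(
    toy_review("R1", c("A", "B"), list("A", "B")),
    toy_review("R2", c("A", "B"), list("A", c("A", "B")))))
  expect_setequal(greedy_cover(corp2, 1, 1), c("A", "B"))

  expect_error(greedy_cover(corp2, 1, 1, candidates = "A"),
               class = "searchrecall_target_unreachable")

  # greedy never beats the exhaustive optimum of equal size
  g <- generate_corpus(small_synth_config(seed = 47, n_reviews = 15))
  target <- 0.9
  chosen <- greedy_cover(g$corpus, target, 0.8, candidates = key_dbs)
  share_of <- function(s) attainment(g$corpus, s, thresholds = target)$share[[1]]
  best_same_size <- max(vapply(combn(key_dbs, length(chosen), simplify = FALSE),
                               share_of, numeric(1)))
  expect_lte(share_of(chosen), best_same_size)
  expect_gte(share_of(chosen), 0.8)
})
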