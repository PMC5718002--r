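test_that("the generator is a pure function of its configuration", {
  cfg <- small_synth_config(seed = 61, n_reviews = 5)
  a <- generate_corpus(cfg)
  b <- generate_corpus(cfg)
  expect_identical(serialize(a, NULL), serialize(b, NULL))
  c2 <- generate_corpus(small_synth_config(seed = 62, n_reviews = 5))
  expect_false(identical(serialize(a$corpus, NULL), serialize(c2$corpus, NULL)))
  # the generator does not disturb the caller's RNG stream
  set.seed(99); x1 <- runif(1)
  set.seed(99); invisible(generate_corpus(cfg)); x2 <- runif(1)
  expect_identical(x1, x2)
})

test_that("certain retrieval leaves no unique references", {
  dbs <- c(EMBASE = 1, MEDLINE = 1, WOS = 1)
  cfg <- synthetic_config(
    n_reviews = 4,
    retrieval_marginals = dbs,
    search_probs = c(EMBASE = 1, MEDLINE = 1, WOS = 1),
    niche_affinity = c(EMBASE = 0.5, MEDLINE = 0.3, WOS = 0.2),
    niche_hit = 1, niche_leak = 1, search_effect_sd = 0,
    other_methods_rate = 0,
    noise_volume = list(pool_mean = 50, pool_size = 8,
                        rates = c(EMBASE = 20, MEDLINE = 15, WOS = 10)),
    seed = 63)
  g <- generate_corpus(cfg)
  for (rv in g$corpus$reviews) {
    expect_true(all(vapply(rv$includes$retrieved_by, setequal, logical(1),
                           rv$searched_databases)))
  }
  expect_true(all(unique_contributions(g$corpus)$n_unique_refs == 0))
})

test_that("impossible calibrations are rejected at configuration time", {
  expect_error(synthetic_config(seed = NULL), class = "searchrecall_config")
  expect_error(
    synthetic_config(retrieval_marginals = c(A = 1.2, B = 0.5),
                     search_probs = c(A = 1, B = 1),
                     niche_affinity = c(A = 0.5, B = 0.5),
                     noise_volume = list(pool_mean = 10, pool_size = 1,
                                         rates = c(A = 1, B = 1)),
                     seed = 1),
    class = "searchrecall_config")
  # marginals of 1 are unreachable when niche includes leak at 0.05
  expect_error(
    synthetic_config(retrieval_marginals = c(A = 1, B = 1),
                     search_probs = c(A = 1, B = 1),
                     niche_affinity = c(A = 0.5, B = 0.5),
                     noise_volume = list(pool_mean = 10, pool_size = 1,
                                         rates = c(A = 1, B = 1)),
                     seed = 1),
    class = "searchrecall_config")
})

test_that("the other-methods share converges to its target rate", {
  g <- generate_corpus(small_synth_config(seed = 64))
  n <- 0; zero <- 0
  for (tr in g$truth$reviews) {
    n <- n + nrow(tr$inc_mat)
    zero <- zero + sum(rowSums(tr$inc_mat) == 0)
  }
  expect_gt(n, 1000)
  rate <- g$truth$config$other_methods_rate
  se <- sqrt(rate * (1 - rate) / n)
  expect_lt(abs(zero / n - rate), 3 * se)
})

test_that("growing overlap_strength shrinks the single-provenance share", {
  # overlap_strength is the mainstream share: with per-database marginals
  # held fixed, more mainstream includes mean fewer niche (one-database)
  # references, the observable that calibrates corpus overlap
  uniq_share <- function(truth) {
    k <- 0; n <- 0
    for (tr in truth$reviews) {
      rs <- rowSums(tr$inc_mat)
      k <- k + sum(rs == 1); n <- n + sum(rs > 0)
    }
    k / n
  }
  us <- vapply(c(0.74, 0.82, 0.9, 0.98), function(w) {
    mean(vapply(1:3, function(s) {
      uniq_share(generate_corpus(small_synth_config(
        seed = 70 + s, n_reviews = 25, overlap_strength = w))$truth)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(us) < 0))
})

test_that("the relevance-ranked database respects its truncation caps", {
  g <- generate_corpus(small_synth_config(seed = 65))
  cfg <- g$truth$config
  gs_counts <- vapply(g$corpus$reviews, function(rv) {
    if (cfg$gs_database %in% names(rv$result_counts))
      rv$result_counts[[cfg$gs_database]] else 0L
  }, integer(1))
  # noise is capped; the cap can only be exceeded by relevant records
  gs_inc <- vapply(g$truth$reviews, function(tr) sum(tr$inc_mat[, cfg$gs_database]),
                   numeric(1))
  expect_true(all(gs_counts <= cfg$gs_rank_cap + gs_inc))
  expect_true(any(gs_counts <= cfg$gs_low_cap + gs_inc))  # low-yield rule fires
  # truncation never sheds relevant records
  expect_true(all(gs_counts >= gs_inc))
})

test_that("the truth recount honors the empty and full conventions", {
  g <- generate_corpus(small_synth_config(seed = 66, n_reviews = 5))
  all_dbs <- g$truth$config$databases
  full <- truth_recount(g$truth, all_dbs)
  expect_true(all(full$per_review$recall == 1))
  empty <- truth_recount(g$truth, character())
  expect_true(all(empty$per_review$includes_retrieved == 0))
  expect_true(all(empty$per_review$results_total == 0))
})

test_that("zero-rate perturbation is the identity", {
  g <- generate_corpus(small_synth_config(seed = 67, n_reviews = 3))
  expect_identical(perturb_titles(g$corpus, 0, seed = 1), g$corpus)
})
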