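lib_row <- function(id, surname, year, title, db, second = NA_character_) {
  tibble::tibble(record_id = id, first_author_surname = surname,
                 second_author_surname = second, year = as.integer(year),
                 title = title, database = db)
}

test_that("match keys normalize case, diacritics and whitespace", {
  expect_equal(build_match_key("Smith", 2015), "smith|2015")
  expect_equal(build_match_key("  SMÍTH ", 2015), "smith|2015")
  expect_equal(build_match_key("van der Berg", 1999), "vanderberg|1999")
  # missing surname yields the sentinel that forces title-stage matching
  expect_equal(build_match_key(NA, 2010), "\x01no-author|2010")
  expect_false(build_match_key(NA, 2010) == build_match_key("no-author", 2010))
})

test_that("duplicate retrievals of one work pool their provenance", {
  lib <- dplyr::bind_rows(
    lib_row("e1", "Smith", 2015, "running and knee injuries", "EMBASE"),
    lib_row("m1", "Smith", 2015, "running and knee injuries", "MEDLINE"),
    lib_row("m2", "Other", 2012, "unrelated work", "MEDLINE"))
  inc <- tibble::tibble(record_id = "i1", first_author_surname = "Smith",
                        second_author_surname = NA_character_, year = 2015L,
                        title = "running and knee injuries",
                        retrieved_by = list(character()), is_included = TRUE)
  res <- match_included(inc, lib)
  expect_equal(res$status, "matched")
  expect_setequal(res$matched_record_ids[[1]], c("e1", "m1"))
  expect_equal(res$provenance[[1]], c("EMBASE", "MEDLINE"))
})

test_that("absent includes come back unmatched with empty provenance", {
  lib <- lib_row("e1", "Smith", 2015, "something", "EMBASE")
  inc <- tibble::tibble(record_id = "i1", first_author_surname = "Nguyen",
                        second_author_surname = NA_character_, year = 2001L,
                        title = "a title", retrieved_by = list(character()),
                        is_included = TRUE)
  res <- match_included(inc, lib)
  expect_equal(res$status, "unmatched")
  expect_length(res$provenance[[1]], 0)
})

test_that("same-key works are disambiguated by title similarity", {
  lib <- dplyr::bind_rows(
    lib_row("a1", "Smith", 2015, "cardiac surgery outcomes in elderly patients", "EMBASE"),
    lib_row("a2", "Smith", 2015, "cardiac surgery outcomes in elderly patients", "WOS"),
    lib_row("b1", "Smith", 2015, "meditation for anxiety in adolescents", "MEDLINE"))
  probe <- function(title) {
    inc <- tibble::tibble(record_id = "i1", first_author_surname = "Smith",
                          second_author_surname = NA_character_, year = 2015L,
                          title = title, retrieved_by = list(character()),
                          is_included = TRUE)
    match_included(inc, lib, title_threshold = 0.6)
  }
  res <- probe("cardiac surgery outcomes in elderly patients")
  expect_equal(res$status, "ambiguous-resolved")
  expect_setequal(res$provenance[[1]], c("EMBASE", "WOS"))

  # oracle: exhaustive pairwise comparison picks the same work
  jac <- function(a, b) {
    ta <- unique(strsplit(normalize_text(a), " ")[[1]])
    tb <- unique(strsplit(normalize_text(b), " ")[[1]])
    length(intersect(ta, tb)) / length(union(ta, tb))
  }
  sims <- vapply(unique(lib$title), jac, numeric(1),
                 b = "cardiac surgery outcomes in elderly patients")
  expect_equal(sort(res$matched_record_ids[[1]]),
               sort(lib$record_id[lib$title == names(which.max(sims))]))

  # neither work similar enough: unmatched, never silently chosen
  expect_equal(probe("completely different words entirely")$status, "unmatched")
})

test_that("threshold ties and second authors behave conservatively", {
  lib <- dplyr::bind_rows(
    lib_row("a1", "Lee", 2010, "alpha beta gamma delta", "EMBASE", second = "Park"),
    lib_row("b1", "Lee", 2010, "alpha beta gamma epsilon", "MEDLINE", second = "Chen"))
  inc <- function(second, title) {
    tibble::tibble(record_id = "i1", first_author_surname = "Lee",
                   second_author_surname = second, year = 2010L,
                   title = title, retrieved_by = list(character()),
                   is_included = TRUE)
  }
  # both works clear the title threshold -> unresolved ambiguity
  res <- match_included(inc(NA_character_, "alpha beta gamma"), lib)
  expect_equal(res$status, "ambiguous-unresolved")
  expect_length(res$provenance[[1]], 0)
  # a second author resolves it before title similarity is consulted
  res2 <- match_included(inc("Chen", "alpha beta gamma"), lib)
  expect_equal(res2$status, "ambiguous-resolved")
  expect_equal(res2$provenance[[1]], "MEDLINE")
})

test_that("attached provenance drives denominators and flags stray ids", {
  g <- generate_corpus(small_synth_config(seed = 21, n_reviews = 2))
  rv <- g$corpus$reviews[[1]]
  res <- match_review(rv)
  res$matched_record_ids[[1]] <- "not-a-record"
  expect_error(attach_provenance(rv, res), class = "searchrecall_consistency")

  # all includes unmatched -> empty retrieved-basis denominator downstream
  rv2 <- g$corpus$reviews[[2]]
  res2 <- match_review(rv2)
  res2$provenance <- replicate(nrow(res2), character(), simplify = FALSE)
  res2$matched_record_ids <- replicate(nrow(res2), character(), simplify = FALSE)
  res2$status <- "unmatched"
  rv2 <- attach_provenance(rv2, res2)
  expect_error(review_recall(rv2, rv2$searched_databases),
               class = "searchrecall_empty_denominator")
})

test_that("matching recovers the ground truth exactly on clean corpora", {
  g <- generate_corpus(small_synth_config(seed = 22, n_reviews = 8))
  for (i in seq_along(g$corpus$reviews)) {
    rv <- g$corpus$reviews[[i]]
    truth_prov <- rv$includes$retrieved_by   # generator-attached truth
    res <- match_review(rv)
    res_again <- match_review(rv)
    expect_identical(res, res_again)         # determinism
    blank <- rv
    blank$includes$retrieved_by <- replicate(nrow(rv$includes), character(),
                                             simplify = FALSE)
    got <- attach_provenance(blank, res)$includes$retrieved_by
    expect_equal(lapply(got, sort), lapply(truth_prov, sort))
  }
})

test_that("case-only perturbation cannot break normalized matching", {
  g <- generate_corpus(small_synth_config(seed = 23, n_reviews = 4))
  pert <- perturb_titles(g$corpus, rate = 1, seed = 5, kinds = "case")
  for (i in seq_along(pert$reviews)) {
    rv <- pert$reviews[[i]]
    got <- attach_provenance(rv, match_review(rv))$includes$retrieved_by
    expect_equal(lapply(got, sort),
                 lapply(g$corpus$reviews[[i]]$includes$retrieved_by, sort))
  }
})

test_that("mixed perturbations yield a measurable, bounded error rate", {
  g <- generate_corpus(small_synth_config(seed = 24, n_reviews = 6))
  pert <- perturb_titles(g$corpus, rate = 0.2, seed = 6)
  n <- 0; wrong <- 0
  for (i in seq_along(pert$reviews)) {
    rv <- pert$reviews[[i]]
    res <- suppressWarnings(match_review(rv))
    got <- suppressWarnings(attach_provenance(rv, res))$includes$retrieved_by
    truth <- g$corpus$reviews[[i]]$includes$retrieved_by
    n <- n + length(truth)
    wrong <- wrong + sum(!mapply(function(a, b) setequal(a, b), got, truth))
  }
  err <- wrong / n
  expect_gte(err, 0)
  expect_lt(err, 0.3)   # perturbing titles only degrades title-stage cases
})
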