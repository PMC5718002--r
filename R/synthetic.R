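#' Synthetic-corpus generator configuration
#'
#' Builds multi-database retrieval corpora with the overlap structure seen
#' in prospectively documented systematic-review searches, together with a
#' ground-truth ledger sufficient to recompute every analysis output by
#' brute force.
#'
#' The membership model for an included reference has two latent classes.
#' With probability `overlap_strength` the include is *mainstream*: every
#' searched database retrieves it independently with an elevated
#' probability. Otherwise it is *niche*: it has an affinity database
#' (drawn from `niche_affinity`, the profile of unique-reference
#' contributions) where retrieval is near-certain (`niche_hit`), and only
#' leaks weakly (`niche_leak`) into other databases. The class
#' probabilities are solved so the pooled per-database marginal equals
#' `retrieval_marginals` exactly; the niche class supplies the negative
#' cross-database dependence that produces realistic unique-reference
#' shares (~17%), which no purely positive-overlap model can reach under
#' these marginals. A review-by-database search-effectiveness random
#' effect (logit scale, sd `search_effect_sd`, offset-corrected so
#' marginals are preserved) reproduces the spread of per-review recall.
#'
#' Includes retrieved by no database are attributed to other search
#' methods; an analytic top-up makes their total share equal
#' `other_methods_rate` in expectation. Irrelevant records are drawn from
#' a per-review candidate pool retrieved independently per database, which
#' yields realistic deduplicated union sizes; the Google-Scholar-like
#' database is relevance-ranked and truncated to `gs_rank_cap` records
#' (`gs_low_cap` when the other databases' yield falls below the
#' `gs_low_quantile` quantile of the corpus, the low-yield rule).
#'
#' @param n_reviews Number of reviews.
#' @param retrieval_marginals Named probabilities that an include is
#'   retrieved by each database (given the review searched it).
#' @param search_probs Named probabilities that a review searches each
#'   database.
#' @param includes_per_review List `mean`, `size` (negative binomial) and
#'   `min` (truncation floor) for the include count per review.
#' @param overlap_strength Mainstream share in \[0, 1\]. With marginals held
#'   fixed, raising it shrinks the niche class and with it the share of
#'   single-provenance (unique) references; the feasible range is bounded
#'   below by the marginals (the mainstream probabilities must stay in
#'   \[0, 1\]).
#' @param niche_affinity Named weights (sum 1) for the niche affinity
#'   database.
#' @param niche_hit,niche_leak Retrieval probabilities of a niche include
#'   in its affinity database and elsewhere.
#' @param search_effect_sd Logit-scale sd of the review-by-database
#'   effectiveness effect (0 disables it).
#' @param noise_volume List: `pool_mean`, `pool_size` (negative binomial
#'   irrelevant candidate pool per review) and named `rates`, the expected
#'   irrelevant records each database retrieves per review.
#' @param gs_database Token of the relevance-ranked, truncated database.
#' @param gs_rank_cap,gs_low_cap,gs_low_quantile Truncation caps and the
#'   low-yield rule quantile.
#' @param other_methods_rate Target share of includes found by no database.
#' @param domain_probs Named probabilities for the review `domain`
#'   metadata.
#' @param domain_shift Optional named logit shifts (by domain) applied to
#'   all retrieval probabilities, for planting recoverable domain effects.
#' @param seed Integer seed; mandatory, every corpus is a pure function of
#'   the configuration.
#' @return A validated `synthetic_config`.
#' @export
synthetic_config <- function(
    n_reviews = 58,
    retrieval_marginals = c(EMBASE = 0.859, MEDLINE = 0.788, WOS = 0.681,
                            GS = 0.344, COCHRANE_CENTRAL = 0.15, SCOPUS = 0.55),
    search_probs = c(EMBASE = 1, MEDLINE = 1, WOS = 1, GS = 1,
                     COCHRANE_CENTRAL = 1, SCOPUS = 0.41),
    includes_per_review = list(mean = 31.6, size = 5, min = 3),
    overlap_strength = 0.78,
    niche_affinity = c(EMBASE = 0.45, MEDLINE = 0.24, WOS = 0.13, GS = 0.13,
                       COCHRANE_CENTRAL = 0.01, SCOPUS = 0.04),
    niche_hit = 0.97, niche_leak = 0.05,
    search_effect_sd = 0.8,
    noise_volume = list(pool_mean = 2500, pool_size = 8,
                        rates = c(EMBASE = 1475, MEDLINE = 971, WOS = 837,
                                  GS = 650, COCHRANE_CENTRAL = 300, SCOPUS = 800)),
    gs_database = "GS", gs_rank_cap = 200, gs_low_cap = 100,
    gs_low_quantile = 0.1,
    other_methods_rate = 0.046,
    domain_probs = c(therapy = 19, etiology = 13, epidemiology = 6,
                     diagnosis = 6, management = 5, prognosis = 5, unknown = 4) / 58,
    domain_shift = NULL,
    seed) {
  if (missing(seed) || is.null(seed) || is.na(seed)) {
    sr_abort("config", "A seed is mandatory: the corpus must be reproducible.")
  }
  dbs <- names(retrieval_marginals)
  chk01 <- function(x, what) {
    if (any(x < 0 | x > 1)) sr_abort("config", sprintf("%s must lie in [0, 1].", what))
  }
  chk01(retrieval_marginals, "retrieval_marginals")
  chk01(search_probs, "search_probs")
  chk01(c(overlap_strength, niche_hit, niche_leak, other_methods_rate,
          gs_low_quantile), "probability parameters")
  if (!setequal(dbs, names(search_probs)) || !setequal(dbs, names(niche_affinity)) ||
      !setequal(dbs, names(noise_volume$rates))) {
    sr_abort("config", "retrieval_marginals, search_probs, niche_affinity and noise_volume$rates must name the same databases.")
  }
  if (abs(sum(niche_affinity) - 1) > 1e-6) {
    sr_abort("config", "niche_affinity weights must sum to 1.")
  }
  if (n_reviews < 1 || gs_rank_cap <= 0 || gs_low_cap <= 0 ||
      includes_per_review$mean <= 0 || noise_volume$pool_mean <= 0) {
    sr_abort("config", "Counts and caps must be positive.")
  }
  w <- overlap_strength
  niche_part <- niche_affinity * niche_hit + (1 - niche_affinity) * niche_leak
  mainstream_p <- (retrieval_marginals - (1 - w) * niche_part[dbs]) / w
  if (any(mainstream_p < 0 | mainstream_p > 1)) {
    sr_abort("config",
             "Marginals are not attainable with these overlap/niche parameters (mainstream probability outside [0, 1]).")
  }
  structure(list(
    n_reviews = as.integer(n_reviews), databases = dbs,
    retrieval_marginals = retrieval_marginals[dbs], search_probs = search_probs[dbs],
    includes_per_review = includes_per_review, overlap_strength = w,
    niche_affinity = niche_affinity[dbs], niche_hit = niche_hit,
    niche_leak = niche_leak, mainstream_p = mainstream_p,
    search_effect_sd = search_effect_sd, noise_volume = noise_volume,
    gs_database = gs_database, gs_rank_cap = as.integer(gs_rank_cap),
    gs_low_cap = as.integer(gs_low_cap), gs_low_quantile = gs_low_quantile,
    other_methods_rate = other_methods_rate, domain_probs = domain_probs,
    domain_shift = domain_shift, seed = as.integer(seed)
  ), class = "synthetic_config")
}

# E[plogis(a + sd * Z)] = p solved for a; identity when sd = 0
solve_logit_offset <- function(p, sd) {
  if (p <= 0) return(-Inf)
  if (p >= 1) return(Inf)
  if (sd == 0) return(qlogis(p))
  f <- function(a) integrate(function(z) plogis(a + sd * z) * stats::dnorm(z),
                             -8, 8)$value - p
  uniroot(f, c(-25, 25))$root
}

# deterministic word/surname pools (no RNG use)
synth_pools <- function() {
  pre <- c("al", "an", "ar", "bar", "ber", "bo", "car", "dal", "de", "el",
           "fer", "gar", "hal", "jan", "kar", "lan", "mar", "nor", "or", "pet",
           "ras", "sol", "tor", "ul", "van", "wil", "yo", "zan")
  suf <- c("berg", "dal", "den", "ders", "gaard", "hof", "kins", "lund",
           "man", "mar", "ney", "quist", "sen", "son", "stein", "stra", "ter", "veld")
  surnames <- toupper(substring(outer(pre, suf, paste0), 1, 1))
  surnames <- paste0(surnames, substring(outer(pre, suf, paste0), 2))
  stems <- c("cardi", "nephr", "neur", "dermat", "gastr", "hepat", "pulmon",
             "arthr", "onc", "hemat", "immun", "endocrin", "psych", "ped",
             "geriatr", "vascul", "metabol", "infect", "muscul", "cerebr")
  ends <- c("ology", "itis", "opathy", "ectomy", "oscopy", "emia", "osis", "al")
  medical <- as.vector(outer(stems, ends, paste0))
  common <- c("randomized", "controlled", "trial", "cohort", "study", "effect",
              "treatment", "outcome", "risk", "patients", "therapy", "chronic",
              "acute", "clinical", "systematic", "analysis", "association",
              "prevalence", "incidence", "management", "diagnosis", "prognosis",
              "intervention", "placebo", "surgery", "rehabilitation", "screening",
              "mortality", "quality", "life", "adults", "children", "elderly",
              "women", "men", "followup", "longterm", "early", "late", "severe")
  list(surnames = surnames, words = c(medical, common))
}

rand_titles <- function(n, words) {
  if (n == 0) return(character())
  len <- sample(5:10, n, replace = TRUE)
  idx <- matrix(sample.int(length(words), n * 10, replace = TRUE), n, 10)
  cols <- as.data.frame(matrix(words[idx], n, 10), stringsAsFactors = FALSE)
  out <- character(n)
  for (L in unique(len)) {
    rows <- len == L
    out[rows] <- do.call(paste, cols[rows, seq_len(L), drop = FALSE])
  }
  out
}

#' Generate a synthetic corpus with its ground-truth ledger
#'
#' @param config A [synthetic_config()].
#' @return List with elements `corpus` (a [corpus()], provenance already
#'   attached to the includes) and `truth` (a `synthetic_truth` ledger:
#'   per-include membership matrices, per-review searched sets, irrelevant
#'   record membership, and the configuration).
#' @export
generate_corpus <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(config$seed)

  dbs <- config$databases
  sv <- config$search_effect_sd
  pools <- synth_pools()
  a_main <- vapply(config$mainstream_p, solve_logit_offset, numeric(1), sd = sv)
  a_hit <- solve_logit_offset(config$niche_hit, sv)
  a_leak <- solve_logit_offset(config$niche_leak, sv)
  w <- config$overlap_strength
  q_noise <- setNames(pmin(1, config$noise_volume$rates[dbs] / config$noise_volume$pool_mean),
                      dbs)

  drafts <- vector("list", config$n_reviews)
  for (r in seq_len(config$n_reviews)) {
    rid <- sprintf("SR%02d", r)
    searched <- dbs[runif(length(dbs)) < config$search_probs]
    if (!length(searched)) searched <- dbs[which.max(config$search_probs)]
    domain <- sample(names(config$domain_probs), 1, prob = config$domain_probs)
    shift <- if (!is.null(config$domain_shift) && domain %in% names(config$domain_shift))
      config$domain_shift[[domain]] else 0
    v <- rnorm(length(dbs), 0, sv)
    names(v) <- dbs
    hh <- plogis(a_main + shift + v)
    aa <- plogis(a_hit + shift + v)
    ee <- plogis(a_leak + shift + v)

    ipr <- config$includes_per_review
    n_inc <- max(ipr$min, rnbinom(1, mu = ipr$mean, size = ipr$size))

    niche <- runif(n_inc) < (1 - w)
    aff <- sample(dbs, n_inc, replace = TRUE, prob = config$niche_affinity)
    pm <- matrix(rep(hh[searched], each = n_inc), n_inc, length(searched),
                 dimnames = list(NULL, searched))
    if (any(niche)) {
      pm[niche, ] <- rep(ee[searched], each = sum(niche))
      hit_cols <- match(aff[niche], searched)
      ok <- !is.na(hit_cols)
      pm[cbind(which(niche)[ok], hit_cols[ok])] <- aa[aff[niche][ok]]
    }
    # analytic zero-retrieval probability of this review's model, for the
    # other-methods top-up
    pz_main <- prod(1 - hh[searched])
    pz_niche <- sum(config$niche_affinity * vapply(dbs, function(a) {
      p <- ee[searched]
      if (a %in% searched) p[searched == a] <- aa[a]
      prod(1 - p)
    }, numeric(1)))
    pz <- w * pz_main + (1 - w) * pz_niche
    r0 <- max(0, (config$other_methods_rate - pz) / (1 - pz))
    upfront <- runif(n_inc) < r0

    inc_mat <- matrix(runif(n_inc * length(searched)), n_inc) < pm
    colnames(inc_mat) <- searched
    inc_mat[upfront, ] <- FALSE

    pool_n <- rnbinom(1, mu = config$noise_volume$pool_mean,
                      size = config$noise_volume$pool_size)
    noise_mat <- matrix(runif(pool_n * length(searched)), pool_n) <
      matrix(rep(q_noise[searched], each = pool_n), pool_n)
    colnames(noise_mat) <- searched
    noise_mat <- noise_mat[rowSums(noise_mat) > 0, , drop = FALSE]

    drafts[[r]] <- list(rid = rid, searched = searched, domain = domain,
                        inc_mat = inc_mat, noise_mat = noise_mat)
  }

  # low-yield rule: reviews whose non-GS yield is in the lowest quantile get
  # the tighter Google-Scholar cap
  gsd <- config$gs_database
  other_yield <- vapply(drafts, function(d) {
    ot <- setdiff(d$searched, gsd)
    sum(d$noise_mat[, ot, drop = FALSE]) + sum(d$inc_mat[, ot, drop = FALSE])
  }, numeric(1))
  low_cut <- quantile(other_yield, config$gs_low_quantile, names = FALSE)

  reviews <- vector("list", config$n_reviews)
  truth_rev <- vector("list", config$n_reviews)
  for (r in seq_len(config$n_reviews)) {
    d <- drafts[[r]]
    searched <- d$searched
    inc_mat <- d$inc_mat
    noise_mat <- d$noise_mat
    if (gsd %in% searched) {
      cap <- if (other_yield[[r]] < low_cut) config$gs_low_cap else config$gs_rank_cap
      # relevance ranking puts the (few) relevant candidates on top, so
      # truncation sheds irrelevant records only
      budget <- max(0L, cap - sum(inc_mat[, gsd]))
      gs_rows <- which(noise_mat[, gsd])
      if (length(gs_rows) > budget) {
        drop_rows <- gs_rows[seq.int(budget + 1L, length(gs_rows))]
        noise_mat[drop_rows, gsd] <- FALSE
        noise_mat <- noise_mat[rowSums(noise_mat) > 0, , drop = FALSE]
      }
    }
    n_inc <- nrow(inc_mat); n_noise <- nrow(noise_mat)
    n_works <- n_inc + n_noise
    surname1 <- sample(pools$surnames, n_works, replace = TRUE)
    surname2 <- ifelse(runif(n_works) < 0.85,
                       sample(pools$surnames, n_works, replace = TRUE), NA_character_)
    years <- sample(1995:2016, n_works, replace = TRUE)
    titles <- rand_titles(n_works, pools$words)

    all_mat <- rbind(inc_mat, noise_mat)
    hitidx <- which(all_mat, arr.ind = TRUE)
    ord <- order(hitidx[, 1], hitidx[, 2])
    hitidx <- hitidx[ord, , drop = FALSE]
    wk <- hitidx[, 1]
    records <- tibble(
      record_id = sprintf("%s-%06d", d$rid, seq_along(wk)),
      first_author_surname = surname1[wk],
      second_author_surname = surname2[wk],
      year = years[wk],
      title = titles[wk],
      database = searched[hitidx[, 2]]
    )
    includes <- tibble(
      record_id = sprintf("%s-I%04d", d$rid, seq_len(n_inc)),
      first_author_surname = surname1[seq_len(n_inc)],
      second_author_surname = surname2[seq_len(n_inc)],
      year = years[seq_len(n_inc)],
      title = titles[seq_len(n_inc)],
      retrieved_by = lapply(seq_len(n_inc), function(i) searched[inc_mat[i, ]]),
      is_included = TRUE
    )
    reviews[[r]] <- review_dataset(d$rid, searched, includes, records = records,
                                   metadata = list(domain = d$domain))
    rownames(inc_mat) <- includes$record_id
    truth_rev[[r]] <- list(review_id = d$rid, searched = searched,
                           domain = d$domain, inc_mat = inc_mat,
                           noise_mat = noise_mat)
  }
  truth <- structure(list(config = config, reviews = truth_rev),
                     class = "synthetic_truth")
  registry <- if (all(dbs %in% names(default_registry()))) default_registry()
              else db_registry(setNames(as.list(dbs), dbs))
  list(corpus = corpus(reviews, registry), truth = truth)
}

#' Brute-force recount from the ground-truth ledger
#'
#' The independent oracle for every combination-analysis output: plain
#' loops over the ledger's membership vectors, no shared code with the
#' analysis pipeline.
#'
#' @param truth A `synthetic_truth` ledger.
#' @param combo Character vector of canonical tokens; the empty combination
#'   scores zero recall by convention.
#' @return List: `per_review` tibble (`review_id`, `includes_retrieved`,
#'   `includes_total`, `results_total`, `recall`) over reviews that
#'   searched the full combination and retrieved at least one include, and
#'   `pooled` (summed counts plus overall recall).
#' @export
truth_recount <- function(truth, combo) {
  stopifnot(inherits(truth, "synthetic_truth"))
  combo <- unique(as.character(combo))
  rows <- list()
  for (tr in truth$reviews) {
    if (!all(combo %in% tr$searched)) next
    inc <- tr$inc_mat
    total <- 0L; hits <- 0L
    for (i in seq_len(nrow(inc))) {
      if (any(inc[i, ])) {
        total <- total + 1L
        if (length(combo) && any(inc[i, combo])) hits <- hits + 1L
      }
    }
    if (total == 0L) next
    results <- 0L
    for (i in seq_len(nrow(inc))) {
      if (length(combo) && any(inc[i, combo])) results <- results + 1L
    }
    nm <- tr$noise_mat
    for (i in seq_len(nrow(nm))) {
      if (length(combo) && any(nm[i, combo])) results <- results + 1L
    }
    rows[[length(rows) + 1L]] <- tibble(
      review_id = tr$review_id, includes_retrieved = hits,
      includes_total = total, results_total = results,
      recall = hits / total)
  }
  per <- dplyr::bind_rows(rows)
  list(per_review = per,
       pooled = list(includes_retrieved = sum(per$includes_retrieved),
                     includes_total = sum(per$includes_total),
                     results_total = sum(per$results_total),
                     overall_recall = if (nrow(per)) sum(per$includes_retrieved) /
                       sum(per$includes_total) else NA_real_))
}

#' Perturb record titles to stress-test matching
#'
#' Applies random case changes, truncations, or diacritic injections to a
#' fraction of the record-level library titles. The bibliographic identity
#' of the works (and the ground truth) is unchanged, so matcher error
#' rates can be measured against the ledger.
#'
#' @param corp A [corpus()].
#' @param rate Fraction of records perturbed, in \[0, 1\].
#' @param seed Integer seed.
#' @param kinds Subset of `c("case", "truncation", "diacritics")`.
#' @return The perturbed corpus.
#' @export
perturb_titles <- function(corp, rate, seed,
                           kinds = c("case", "truncation", "diacritics")) {
  stopifnot(rate >= 0, rate <= 1)
  kinds <- match.arg(kinds, several.ok = TRUE)
  if (rate == 0) return(corp)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  corp$reviews <- lapply(corp$reviews, function(rv) {
    if (is.null(rv$records) || !nrow(rv$records)) return(rv)
    n <- nrow(rv$records)
    sel <- which(runif(n) < rate)
    if (!length(sel)) return(rv)
    kind <- sample(kinds, length(sel), replace = TRUE)
    tt <- rv$records$title
    up <- sel[kind == "case"]
    tt[up] <- toupper(tt[up])
    tr <- sel[kind == "truncation"]
    tt[tr] <- vapply(tt[tr], function(x) {
      wds <- strsplit(x, " ", fixed = TRUE)[[1]]
      paste(wds[seq_len(max(1, ceiling(0.6 * length(wds))))], collapse = " ")
    }, character(1), USE.NAMES = FALSE)
    di <- sel[kind == "diacritics"]
    tt[di] <- chartr("aeiou", "áéíóú", tt[di])
    rv$records$title <- tt
    rv
  })
  corp
}
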