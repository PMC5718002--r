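#' Combination key
#'
#' Canonical printable form of a database combination: sorted tokens joined
#' by `+` (e.g. `"EMBASE+GS+MEDLINE"`). Used as the join key between
#' performance tables, attainment tables and practice samples.
#'
#' @param combo Character vector of canonical tokens.
#' @return A single string (empty combo gives `""`).
#' @export
combo_key <- function(combo) paste(sort(unique(as.character(combo))), collapse = "+")

# Per-review matrices used by all combination operations:
#   inc_mat  - includes x searched databases (provenance membership)
#   work_mat - distinct works x searched databases (record-level, after
#              collapsing duplicate retrievals of the same work)
prep_review <- function(review) {
  dbs <- review$searched_databases
  inc <- review$includes
  inc_mat <- matrix(FALSE, nrow(inc), length(dbs), dimnames = list(NULL, dbs))
  for (j in seq_along(dbs)) {
    inc_mat[, j] <- vapply(inc$retrieved_by, function(p) dbs[[j]] %in% p, logical(1))
  }
  work_mat <- NULL
  if (!is.null(review$records) && nrow(review$records)) {
    sig <- work_signature(review$records)
    usig <- unique(sig)
    work_mat <- vapply(dbs, function(d) usig %in% sig[review$records$database == d],
                       logical(length(usig)))
    if (is.null(dim(work_mat))) work_mat <- matrix(work_mat, nrow = 1, dimnames = list(NULL, dbs))
  }
  list(review_id = review$review_id, dbs = dbs, counts = review$result_counts,
       inc_mat = inc_mat, n_retrieved = sum(rowSums(inc_mat) > 0),
       work_mat = work_mat, metadata = review$metadata)
}

prep_corpus <- function(corp) lapply(corp$reviews, prep_review)

# evaluate one combination on prepped reviews (all of which searched combo)
eval_on_prep <- function(preps, combo, dedup = c("auto", "records", "counts")) {
  dedup <- match.arg(dedup)
  have_records <- all(vapply(preps, function(p) !is.null(p$work_mat), logical(1)))
  use_records <- switch(dedup, records = TRUE, counts = FALSE, auto = have_records)
  if (use_records && !have_records) {
    sr_abort("validation", "Record-level deduplication requested but some reviews carry counts only.")
  }
  per <- lapply(preps, function(p) {
    hits <- sum(rowSums(p$inc_mat[, combo, drop = FALSE]) > 0)
    results <- if (use_records) {
      sum(rowSums(p$work_mat[, combo, drop = FALSE]) > 0)
    } else {
      sum(p$counts[combo])
    }
    c(hits = hits, denom = p$n_retrieved, results = results)
  })
  m <- do.call(rbind, per)
  recalls <- m[, "hits"] / m[, "denom"]
  inc_ret <- sum(m[, "hits"]); inc_tot <- sum(m[, "denom"]); res_tot <- sum(m[, "results"])
  ck <- combo_key(combo)
  tibble(
    combo = list(sort(combo)), combo_key = ck,
    n_reviews = nrow(m),
    results_total = res_tot,
    includes_retrieved = inc_ret,
    includes_total = inc_tot,
    overall_recall = recall(inc_ret, inc_tot),
    median_recall = median(recalls),
    min_recall = min(recalls),
    pct_full_recall = mean(recalls >= 1),
    precision = if (res_tot > 0) inc_ret / res_tot else NA_real_,
    nnr = if (inc_ret > 0) res_tot / inc_ret else NA_real_,
    dedup = if (use_records) "records" else "counts"
  )
}

#' Evaluate one database combination over a corpus
#'
#' Pools the combination's retrieval over every review that searched all of
#' its members (reviews that skipped a member are excluded rather than
#' scored zero) and reports the full performance row: deduplicated result
#' count, includes retrieved, overall / median / minimum recall, share of
#' reviews at 100% recall, precision, and NNR. Result counts are exact
#' record-level union sizes when record-level libraries are available;
#' otherwise the per-database counts recorded at search time are summed and
#' the row is flagged `dedup = "counts"`.
#'
#' Reviews with no retrieved includes carry no recall information and are
#' excluded from evaluation.
#'
#' @param corp A [corpus()] with provenance attached.
#' @param combo Character vector of canonical tokens.
#' @param dedup `"auto"` (records when available), `"records"`, or `"counts"`.
#' @return One-row performance tibble.
#' @export
evaluate_combination <- function(corp, combo, dedup = c("auto", "records", "counts")) {
  combo <- sort(unique(as.character(combo)))
  stopifnot(length(combo) >= 1)
  revs <- evaluable_reviews(corp, combo)
  revs <- revs[vapply(revs, function(r) any(lengths(r$includes$retrieved_by) > 0), logical(1))]
  if (!length(revs)) {
    sr_abort("no_evaluable_review",
             sprintf("No review searched all of: %s", paste(combo, collapse = ", ")))
  }
  eval_on_prep(lapply(revs, prep_review), combo, dedup)
}

#' Evaluate every non-empty subset of candidate databases
#'
#' One performance row per subset, ordered by subset size then
#' lexicographic key, as in an exhaustive combination table (4 candidates
#' give 15 rows).
#'
#' @inheritParams evaluate_combination
#' @param candidates Character vector of canonical tokens (at most 12).
#' @return Performance tibble with `2^length(candidates) - 1` rows.
#' @export
evaluate_all_subsets <- function(corp, candidates, dedup = c("auto", "records", "counts")) {
  candidates <- sort(unique(as.character(candidates)))
  if (length(candidates) < 1) sr_abort("validation", "Need at least one candidate database.")
  if (length(candidates) > 12) {
    sr_abort("too_many_candidates",
             sprintf("%d candidates would enumerate %s subsets; the cap is 12.",
                     length(candidates), format(2^length(candidates) - 1, big.mark = ",")))
  }
  subsets <- all_subsets(candidates)
  preps_all <- prep_corpus(corp)
  rows <- lapply(subsets, function(s) {
    keep <- vapply(preps_all, function(p) all(s %in% p$dbs) && p$n_retrieved > 0, logical(1))
    if (!any(keep)) {
      sr_abort("no_evaluable_review",
               sprintf("No review searched all of: %s", paste(s, collapse = ", ")))
    }
    eval_on_prep(preps_all[keep], s, dedup)
  })
  dplyr::bind_rows(rows)
}

all_subsets <- function(candidates) {
  n <- length(candidates)
  subs <- unlist(lapply(seq_len(n), function(k) {
    m <- utils::combn(candidates, k, simplify = FALSE)
    m[order(vapply(m, combo_key, character(1)))]
  }), recursive = FALSE)
  subs
}

#' Unique-reference contributions per database
#'
#' A *unique* reference is an include whose provenance contains exactly one
#' database. For each database the table reports how many reviews searched
#' it, in how many of those it contributed at least one unique reference,
#' and the total unique references. The grand total of single-provenance
#' includes and its share of all retrieved includes are attached as
#' attributes `n_unique_total` and `unique_share`.
#'
#' @param corp A [corpus()] with provenance attached.
#' @return Tibble sorted by unique references, descending.
#' @export
unique_contributions <- function(corp) {
  dbs <- sort(unique(unlist(lapply(corp$reviews, function(r) r$searched_databases))))
  per_db <- lapply(dbs, function(d) {
    used <- vapply(corp$reviews, function(r) d %in% r$searched_databases, logical(1))
    uniq <- vapply(corp$reviews[used], function(r) {
      sum(vapply(r$includes$retrieved_by, function(p) length(p) == 1 && p == d, logical(1)))
    }, numeric(1))
    tibble(database = d, n_reviews_used = sum(used),
           n_reviews_with_unique = sum(uniq > 0), n_unique_refs = sum(uniq))
  })
  out <- dplyr::arrange(dplyr::bind_rows(per_db), dplyr::desc(.data$n_unique_refs),
                        dplyr::desc(.data$n_reviews_with_unique), .data$database)
  prov_len <- unlist(lapply(corp$reviews, function(r) lengths(r$includes$retrieved_by)))
  attr(out, "n_unique_total") <- sum(prov_len == 1)
  attr(out, "unique_share") <- sum(prov_len == 1) / max(1L, sum(prov_len > 0))
  out
}

#' Select candidate databases by unique contribution
#'
#' Takes the top `k` databases by unique included references, breaking ties
#' by the number of reviews with unique references and then by canonical
#' name, so the selection is deterministic.
#'
#' @param contributions Output of [unique_contributions()].
#' @param k Number of candidates.
#' @return Ordered character vector of canonical tokens.
#' @export
select_candidates <- function(contributions, k) {
  stopifnot(k >= 1)
  ord <- order(-contributions$n_unique_refs, -contributions$n_reviews_with_unique,
               contributions$database)
  head(contributions$database[ord], k)
}

#' Attainment: share of reviews reaching a recall threshold
#'
#' For each threshold, the share of evaluable reviews in which the
#' combination's recall reaches the threshold. The comparison is `>=` by
#' default (`threshold = 1` then equals the percentage-100%-recall column);
#' strict `>` is available because prose descriptions of such thresholds
#' are often ambiguous.
#'
#' @inheritParams evaluate_combination
#' @param thresholds Fractions in (0, 1\], conventionally
#'   `c(1, 0.95, 0.90, 0.80)`.
#' @param comparator `">="` or `">"`.
#' @return Tibble: `combo_key`, `threshold`, `n_reviews`, `share`.
#' @export
attainment <- function(corp, combo, thresholds = c(1, 0.95, 0.90, 0.80),
                       comparator = c(">=", ">")) {
  comparator <- match.arg(comparator)
  stopifnot(all(thresholds > 0), all(thresholds <= 1))
  combo <- sort(unique(as.character(combo)))
  revs <- evaluable_reviews(corp, combo)
  revs <- revs[vapply(revs, function(r) any(lengths(r$includes$retrieved_by) > 0), logical(1))]
  if (!length(revs)) {
    sr_abort("no_evaluable_review",
             sprintf("No review searched all of: %s", paste(combo, collapse = ", ")))
  }
  recalls <- vapply(revs, review_recall, numeric(1), combo = combo)
  cmp <- if (comparator == ">=") `>=` else `>`
  tibble(combo_key = combo_key(combo),
         threshold = sort(thresholds, decreasing = TRUE),
         n_reviews = length(recalls),
         share = vapply(sort(thresholds, decreasing = TRUE),
                        function(t) mean(cmp(recalls, t)), numeric(1)))
}

#' Attainment stratified by a metadata key
#'
#' Splits the evaluable reviews by a metadata field (e.g. `domain`) and
#' computes [attainment()] within each group. Reviews lacking the key form
#' the group `"unknown"`.
#'
#' @inheritParams attainment
#' @param group_key Metadata key to stratify on.
#' @return Tibble with a leading `group` column.
#' @export
stratified_attainment <- function(corp, combo, group_key,
                                  thresholds = c(1, 0.95, 0.90, 0.80),
                                  comparator = c(">=", ">")) {
  comparator <- match.arg(comparator)
  combo <- sort(unique(as.character(combo)))
  revs <- evaluable_reviews(corp, combo)
  revs <- revs[vapply(revs, function(r) any(lengths(r$includes$retrieved_by) > 0), logical(1))]
  groups <- vapply(revs, function(r) {
    g <- r$metadata[[group_key]]
    if (is.null(g) || is.na(g) || !nzchar(g)) "unknown" else as.character(g)
  }, character(1))
  recalls <- vapply(revs, review_recall, numeric(1), combo = combo)
  cmp <- if (comparator == ">=") `>=` else `>`
  th <- sort(thresholds, decreasing = TRUE)
  dplyr::bind_rows(lapply(sort(unique(groups)), function(g) {
    rc <- recalls[groups == g]
    tibble(group = g, combo_key = combo_key(combo), threshold = th,
           n_reviews = length(rc),
           share = vapply(th, function(t) mean(cmp(rc, t)), numeric(1)))
  }))
}

review_union_size <- function(review, combo) {
  if (!is.null(review$records) && nrow(review$records)) {
    sig <- work_signature(review$records)
    length(unique(sig[review$records$database %in% combo]))
  } else {
    sum(review$result_counts[intersect(combo, names(review$result_counts))])
  }
}

#' Results-reduction ratio for one review
#'
#' Deduplicated results retrieved by the combination divided by the
#' deduplicated results of the review's full searched set: how much
#' screening burden remains when only the combination is searched. 1 for
#' the full set, 0 for a combination that retrieved nothing.
#'
#' @inheritParams review_recall
#' @return A fraction.
#' @export
results_reduction_ratio <- function(review, combo) {
  combo <- unique(as.character(combo))
  if (!all(combo %in% review$searched_databases)) {
    sr_abort("combination_not_searched",
             sprintf("Review %s did not search: %s", sQuote(review$review_id),
                     paste(setdiff(combo, review$searched_databases), collapse = ", ")))
  }
  total <- review_union_size(review, review$searched_databases)
  check_positive_denominator(total, sprintf("total results of review %s", review$review_id))
  review_union_size(review, combo) / total
}

#' Precision-improvement ratio for one review
#'
#' Ratio of the combination's precision to the precision of searching the
#' review's full database set. Values above 1 mean the combination is
#' *more* precise than searching everything (it sheds more irrelevant
#' records than relevant ones); 1 for the full set itself.
#'
#' @inheritParams review_recall
#' @return A positive number.
#' @export
precision_improvement_ratio <- function(review, combo) {
  combo <- unique(as.character(combo))
  if (!all(combo %in% review$searched_databases)) {
    sr_abort("combination_not_searched",
             sprintf("Review %s did not search: %s", sQuote(review$review_id),
                     paste(setdiff(combo, review$searched_databases), collapse = ", ")))
  }
  hits_combo <- sum(include_provenance_hits(review, combo))
  hits_all <- sum(lengths(review$includes$retrieved_by) > 0)
  res_combo <- review_union_size(review, combo)
  res_all <- review_union_size(review, review$searched_databases)
  check_positive_denominator(res_combo, sprintf("combination results in review %s", review$review_id))
  check_positive_denominator(hits_all, sprintf("retrieved includes in review %s", review$review_id))
  check_positive_denominator(res_all, sprintf("total results in review %s", review$review_id))
  (hits_combo / res_combo) / (hits_all / res_all)
}

#' Per-review ratio distributions over a corpus
#'
#' The corpus-level counterpart of [results_reduction_ratio()] and
#' [precision_improvement_ratio()]: the per-review ratio distribution that
#' box-plot style summaries are drawn from, for one combination or a list
#' of combinations (record-level deduplication is prepared once, so
#' evaluating the full subset lattice stays cheap).
#'
#' @inheritParams evaluate_combination
#' @param combos One combination (character vector) or a list of them.
#' @param ratio `"reduction"` or `"precision"`.
#' @return Tibble: `review_id`, `combo_key`, `ratio`.
#' @export
corpus_ratios <- function(corp, combos, ratio = c("reduction", "precision")) {
  ratio <- match.arg(ratio)
  if (!is.list(combos)) combos <- list(combos)
  combos <- lapply(combos, function(x) sort(unique(as.character(x))))
  preps <- prep_corpus(corp)
  preps <- preps[vapply(preps, function(p) p$n_retrieved > 0, logical(1))]
  one <- function(p, cb) {
    if (!is.null(p$work_mat)) {
      res_cb <- sum(rowSums(p$work_mat[, cb, drop = FALSE]) > 0)
      res_all <- nrow(p$work_mat)
    } else {
      res_cb <- sum(p$counts[cb])
      res_all <- sum(p$counts)
    }
    check_positive_denominator(res_all, sprintf("total results of review %s", p$review_id))
    if (ratio == "reduction") return(res_cb / res_all)
    hits_cb <- sum(rowSums(p$inc_mat[, cb, drop = FALSE]) > 0)
    check_positive_denominator(res_cb, sprintf("combination results in review %s", p$review_id))
    (hits_cb / res_cb) / (p$n_retrieved / res_all)
  }
  dplyr::bind_rows(lapply(combos, function(cb) {
    ps <- preps[vapply(preps, function(p) all(cb %in% p$dbs), logical(1))]
    if (!length(ps)) {
      sr_abort("no_evaluable_review",
               sprintf("No review searched all of: %s", paste(cb, collapse = ", ")))
    }
    tibble(review_id = vapply(ps, function(p) p$review_id, character(1)),
           combo_key = combo_key(cb),
           ratio = vapply(ps, one, numeric(1), cb = cb))
  }))
}

#' Greedy database selection toward a recall target
#'
#' Iteratively adds the database with the best marginal gain in the share
#' of reviews reaching `target_recall`, per unit cost, until
#' `target_share_of_reviews` of reviews reach the target or the candidates
#' are exhausted. Tie-breaking is deterministic (larger gain, then
#' canonical name). Errors if even the full candidate set cannot reach the
#' target share.
#'
#' @inheritParams evaluate_combination
#' @param target_recall Per-review recall to reach, in (0, 1\].
#' @param target_share_of_reviews Required share of reviews reaching it.
#' @param candidates Databases to choose from; defaults to every database
#'   searched by any review.
#' @param costs Named numeric cost per database; defaults to 1 each.
#' @return Ordered character vector of selected databases.
#' @export
greedy_cover <- function(corp, target_recall, target_share_of_reviews,
                         candidates = NULL, costs = NULL) {
  stopifnot(target_recall > 0, target_recall <= 1,
            target_share_of_reviews > 0, target_share_of_reviews <= 1)
  if (is.null(candidates)) {
    candidates <- sort(unique(unlist(lapply(corp$reviews, function(r) r$searched_databases))))
  }
  if (is.null(costs)) costs <- setNames(rep(1, length(candidates)), candidates)
  share_of <- function(s) {
    at <- attainment(corp, s, thresholds = target_recall)
    at$share[[1]]
  }
  full <- share_of(candidates)
  if (full < target_share_of_reviews) {
    sr_abort("target_unreachable",
             sprintf("Even the full candidate set reaches only %.1f%% of reviews (target %.1f%%).",
                     100 * full, 100 * target_share_of_reviews))
  }
  chosen <- character()
  repeat {
    if (length(chosen) && share_of(chosen) >= target_share_of_reviews) break
    left <- setdiff(candidates, chosen)
    if (!length(left)) break
    base <- if (length(chosen)) share_of(chosen) else 0
    gain <- vapply(left, function(d) (share_of(c(chosen, d)) - base) / costs[[d]], numeric(1))
    best <- left[order(-gain, left)][[1]]
    chosen <- c(chosen, best)
  }
  chosen
}
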