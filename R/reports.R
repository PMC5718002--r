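#' Percent formatting with round-half-up
#'
#' Performance tables print percentages at one decimal ("98.3%"), practice
#' tables at whole percents ("40%"). Ties round up (0.05 -> 0.1), matching
#' hand-computed tables rather than IEEE banker's rounding. Fractions are
#' kept at full precision internally; formatting happens only at report
#' time.
#'
#' @param x Fractions in \[0, 1\].
#' @param digits Decimal places of the printed percentage.
#' @return Character vector like `"98.3%"`.
#' @examples
#' format_pct(0.98281)      # "98.3%"
#' format_pct(0.405, 0)     # "41%"
#' @export
format_pct <- function(x, digits = 1) {
  ifelse(is.na(x), NA_character_,
         paste0(formatC(round_half_up(100 * x, digits), format = "f",
                        digits = digits), "%"))
}

round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  floor(x * p + 0.5 + 1e-9) / p
}

parse_pct <- function(x) as.numeric(sub("%$", "", x)) / 100

#' Format a combination-performance table for reporting
#'
#' Renders the output of [evaluate_all_subsets()] (or a single
#' [evaluate_combination()] row) with the conventional nine columns:
#' combination, number of results, number of includes, overall / median /
#' minimum recall, percentage of reviews with 100% recall, precision, and
#' number needed to read. Recall and precision print at one decimal, NNR at
#' the nearest integer.
#'
#' @param perf Tibble of combination performance rows.
#' @return A tibble of formatted character/integer columns.
#' @export
report_performance <- function(perf) {
  tibble(
    combination = perf$combo_key,
    n_results = perf$results_total,
    n_includes = perf$includes_retrieved,
    overall_recall = format_pct(perf$overall_recall),
    median_recall = format_pct(perf$median_recall),
    min_recall = format_pct(perf$min_recall),
    pct_full_recall = format_pct(perf$pct_full_recall),
    precision = format_pct(perf$precision),
    nnr = as.integer(round_half_up(perf$nnr))
  )
}

#' Write analysis reports as CSV tables
#'
#' Emits whichever of the following the `results` list carries:
#' `unique_contributions` (database, reviews used, reviews with unique
#' references, unique references), `performance` (the nine-column
#' combination table), `attainment`, `stratified_attainment`,
#' `reduction_ratios`, `precision_ratios`, and `practice` (combination,
#' frequency, probabilities at whole percents).
#'
#' @param results Named list of analysis outputs.
#' @param out_dir Output directory, created if needed.
#' @return Character vector of written paths, invisibly.
#' @export
write_reports <- function(results, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  emit <- function(df, name) {
    p <- file.path(out_dir, paste0(name, ".csv"))
    tryCatch(readr::write_csv(df, p, progress = FALSE),
             error = function(e) sr_abort("io", sprintf("Failed writing %s: %s",
                                                        p, conditionMessage(e))))
    written <<- c(written, p)
  }
  if (!is.null(results$unique_contributions)) {
    uc <- results$unique_contributions
    emit(tibble(database = uc$database,
                n_reviews_used = uc$n_reviews_used,
                n_reviews_with_unique = uc$n_reviews_with_unique,
                n_unique_refs = uc$n_unique_refs),
         "unique_contributions")
  }
  if (!is.null(results$performance)) {
    emit(report_performance(results$performance), "performance")
  }
  if (!is.null(results$attainment)) {
    at <- results$attainment
    emit(tibble(combination = at$combo_key, threshold = at$threshold,
                pct_reviews = format_pct(at$share)), "attainment")
  }
  if (!is.null(results$stratified_attainment)) {
    at <- results$stratified_attainment
    emit(tibble(group = at$group, combination = at$combo_key,
                threshold = at$threshold, pct_reviews = format_pct(at$share)),
         "stratified_attainment")
  }
  if (!is.null(results$reduction_ratios)) emit(results$reduction_ratios, "reduction_ratios")
  if (!is.null(results$precision_ratios)) emit(results$precision_ratios, "precision_ratios")
  if (!is.null(results$practice)) {
    pr <- results$practice
    pct_cols <- grep("^prob_|^share", names(pr), value = TRUE)
    for (cc in pct_cols) pr[[cc]] <- format_pct(pr[[cc]], 0)
    emit(pr, "practice")
  }
  invisible(written)
}
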