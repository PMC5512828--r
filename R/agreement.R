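#' Documented-versus-calculated risk pairs
#'
#' For every patient with at least one clinician-documented risk score, the
#' first documented score (by date; file order breaks ties) is paired with
#' the risk category recalculated from the record: the index date is the
#' documentation date, SBP and TC are selected retrospectively (most recent
#' strictly before the index), missing values are imputed, and the chart is
#' applied. Patients with a CVD history appear on the calculated side as
#' `history_of_cvd` rather than a chart score. Patients with no documented
#' score contribute nothing.
#'
#' @param cohort An [emr_cohort()].
#' @param chart A `whoish_chart`.
#' @param model A `tc_model` from [fit_tc_model()].
#' @param config A configuration list, see [default_config()].
#' @return A tibble with columns `patient_id`, `documented` (ordered
#'   factor over [risk_levels()]) and `calculated` (factor over
#'   [calculated_levels()]).
#' @export
documented_accuracy_pairs <- function(cohort, chart, model,
                                      config = default_config()) {
  cohort <- as_emr_cohort(cohort)
  d <- cohort$documented_scores
  if (nrow(d) == 0) {
    return(tibble::tibble(patient_id = character(),
                          documented = as_risk_category(character()),
                          calculated = as_risk_category(character(), extended = TRUE)))
  }
  d <- d[order(d$patient_id, as.numeric(as.Date(d$date))), ]
  first_doc <- d[!duplicated(d$patient_id), ]
  index <- tibble::tibble(patient_id = first_doc$patient_id,
                          index_date = as.Date(first_doc$date))
  vals <- contextual_values(cohort, index, direction = "retrospective",
                            model = model, config = config)
  risk <- calculate_risk(vals, chart)
  cvd <- has_cvd_history(vals$conditions)
  calc <- ifelse(cvd, "history_of_cvd", as.character(risk))
  tibble::tibble(
    patient_id = first_doc$patient_id,
    documented = as_risk_category(first_doc$category),
    calculated = as_risk_category(calc, extended = TRUE)
  )
}

#' Cross-tabulate documented against calculated risk
#'
#' @param pairs Output of [documented_accuracy_pairs()].
#' @param square Extend the documented margin with an (empty)
#'   `history_of_cvd` level so the table is square, as required for the
#'   six-level kappa.
#' @return An integer contingency matrix (documented rows, calculated
#'   columns).
#' @export
agreement_table <- function(pairs, square = FALSE) {
  doc <- if (square) {
    factor(as.character(pairs$documented), levels = calculated_levels())
  } else {
    as_risk_category(pairs$documented)
  }
  unclass(table(documented = doc,
                calculated = as_risk_category(pairs$calculated, extended = TRUE)))
}

#' Aggregate an agreement table at the 20% threshold
#'
#' Collapses the 5 x 6 documented-by-calculated table to 2 x 2 over
#' high (>= 20%) and low (< 20%) risk. Patients with a history of CVD are
#' categorised as high risk on the calculated side. Counts are conserved.
#'
#' @param tab A documented-by-calculated table from [agreement_table()].
#' @return A 2 x 2 integer matrix with rows/columns `>=20` then `<20`.
#' @export
aggregate_binary <- function(tab) {
  hi_doc <- rownames(tab) %in% c("20-<30", "30-<40", ">=40")
  hi_calc <- colnames(tab) %in% c("20-<30", "30-<40", ">=40", "history_of_cvd")
  matrix(
    c(sum(tab[hi_doc, hi_calc]), sum(tab[hi_doc, !hi_calc]),
      sum(tab[!hi_doc, hi_calc]), sum(tab[!hi_doc, !hi_calc])),
    nrow = 2, byrow = TRUE,
    dimnames = list(documented = c(">=20", "<20"), calculated = c(">=20", "<20"))
  )
}

#' CVD match rule for kappa
#'
#' Clinicians cannot chart-score secondary-prevention patients, so a
#' documented score of at least 20% for a patient with existing CVD is
#' treated as correct: the calculated side of such a pair is rewritten to
#' equal the documented category before computing kappa. All other pairs
#' are unchanged; the rewrite can only increase diagonal mass.
#'
#' @param pairs Output of [documented_accuracy_pairs()].
#' @return The pairs with the match rule applied.
#' @export
apply_cvd_match_rule <- function(pairs) {
  hit <- pairs$calculated == "history_of_cvd" & is_high_risk(pairs$documented)
  calc <- as.character(pairs$calculated)
  calc[hit] <- as.character(pairs$documented)[hit]
  pairs$calculated <- as_risk_category(calc, extended = TRUE)
  pairs
}

#' Cohen's kappa
#'
#' Chance-corrected agreement kappa = (p_o - p_e) / (1 - p_e), with
#' observed agreement p_o the diagonal share and expected agreement p_e
#' from the product of the marginal distributions. Returns `NA` (with a
#' warning) when the expected agreement is 1, where kappa is undefined.
#'
#' @param tab A square contingency matrix with matching row/column
#'   categories.
#' @return A single numeric value in \[-1, 1\], or `NA` when undefined.
#' @export
#' @examples
#' cohen_kappa(matrix(c(19, 6, 130, 525), 2, byrow = TRUE))
cohen_kappa <- function(tab) {
  tab <- as.matrix(tab)
  if (nrow(tab) != ncol(tab)) {
    stop("Cohen's kappa requires a square table", call. = FALSE)
  }
  n <- sum(tab)
  if (n < 1) stop("empty table", call. = FALSE)
  p_o <- sum(diag(tab)) / n
  p_e <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (p_e >= 1) {
    warning("kappa undefined: expected agreement is 1", call. = FALSE)
    return(NA_real_)
  }
  (p_o - p_e) / (1 - p_e)
}

#' Binomial proportion confidence intervals
#'
#' `wilson_cc` is the Wilson score interval with continuity correction;
#' `exact` is the Clopper-Pearson interval (via [stats::binom.test()]).
#' Both are clipped to \[0, 1\]; the lower bound is 0 when `x = 0` and the
#' upper bound 1 when `x = n`.
#'
#' @param x Number of successes (0 <= x <= n).
#' @param n Number of trials (>= 1).
#' @param method `"wilson_cc"` (default) or `"exact"`.
#' @param conf_level Confidence level (default 0.95).
#' @return Named numeric vector `c(lower, upper)` on the proportion scale.
#' @export
#' @examples
#' round(proportion_ci(4, 11, "wilson_cc"), 3)  # 0.124, 0.684
proportion_ci <- function(x, n, method = c("wilson_cc", "exact"),
                          conf_level = 0.95) {
  method <- match.arg(method)
  if (length(x) != 1 || length(n) != 1 || is.na(x) || is.na(n) ||
      n < 1 || x < 0 || x > n) {
    stop("need 0 <= x <= n with n >= 1", call. = FALSE)
  }
  if (method == "exact") {
    ci <- stats::binom.test(x, n, conf.level = conf_level)$conf.int
    return(c(lower = ci[1], upper = ci[2]))
  }
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  p <- x / n
  lower <- if (x == 0) 0 else {
    (2 * n * p + z^2 - 1 - z * sqrt(z^2 - 2 - 1 / n + 4 * p * (n * (1 - p) + 1))) /
      (2 * (n + z^2))
  }
  upper <- if (x == n) 1 else {
    (2 * n * p + z^2 + 1 + z * sqrt(z^2 + 2 - 1 / n + 4 * p * (n * (1 - p) - 1))) /
      (2 * (n + z^2))
  }
  c(lower = max(0, lower), upper = min(1, upper))
}

#' Share of documented scores that match the calculation
#'
#' The diagonal share of a documented-by-calculated agreement table: the
#' proportion of documented scores whose category equals the recalculated
#' category. `history_of_cvd` has no documented counterpart in the raw
#' table, so CVD pairs can only count as matches after
#' [apply_cvd_match_rule()].
#'
#' @param tab A table from [agreement_table()] (5 x 6 or square 6 x 6).
#' @return Proportion in \[0, 1\].
#' @export
percent_correct <- function(tab) {
  shared <- intersect(rownames(tab), colnames(tab))
  sum(diag(as.matrix(tab)[shared, shared])) / sum(tab)
}

#' Agreement analysis summary
#'
#' Bundles the full agreement analysis for a set of documented/calculated
#' pairs: the 5 x 6 table, the 2 x 2 threshold aggregation, the diagonal
#' match proportion, misclassification proportions with confidence
#' intervals, and both kappa variants (2 x 2 on the threshold table, and
#' 6-level square after the CVD match rule, retaining the residual
#' `history_of_cvd` column for CVD patients documented below 20%).
#'
#' @inheritParams documented_accuracy_pairs
#' @param pairs Output of [documented_accuracy_pairs()].
#' @return A list of class `agreement_summary`.
#' @export
summarise_agreement <- function(pairs, config = default_config()) {
  tab <- agreement_table(pairs)
  bin <- aggregate_binary(tab)
  matched <- apply_cvd_match_rule(pairs)
  sq <- agreement_table(matched, square = TRUE)
  n <- sum(tab)
  doc_high <- sum(bin[">=20", ])
  doc_low <- sum(bin["<20", ])
  ci <- function(x, m) {
    if (m == 0) c(lower = NA_real_, upper = NA_real_)
    else proportion_ci(x, m, config$ci_method, config$conf_level)
  }
  structure(list(
    n = n,
    table = tab,
    table_binary = bin,
    table_square_matched = sq,
    prop_correct = percent_correct(tab),
    prop_correct_matched = percent_correct(sq),
    prop_doc_high_actually_low = if (doc_high > 0) bin[">=20", "<20"] / doc_high else NA_real_,
    ci_doc_high_actually_low = ci(bin[">=20", "<20"], doc_high),
    prop_doc_low_actually_high = if (doc_low > 0) bin["<20", ">=20"] / doc_low else NA_real_,
    ci_doc_low_actually_high = ci(bin["<20", ">=20"], doc_low),
    kappa_binary = if (n > 0) cohen_kappa(bin) else NA_real_,
    kappa_matched = if (n > 0) cohen_kappa(sq) else NA_real_
  ), class = "agreement_summary")
}

#' @export
print.agreement_summary <- function(x, ...) {
  cat("<agreement_summary> n =", x$n, "documented scores\n")
  if (x$n == 0) return(invisible(x))
  cat(sprintf("  correct (diagonal): %.0f%%\n", 100 * x$prop_correct))
  cat(sprintf("  kappa (2x2 at 20%% threshold): %.3f\n", x$kappa_binary))
  cat(sprintf("  kappa (6-level, CVD match rule): %.3f\n", x$kappa_matched))
  cat(sprintf("  documented high but calculated low: %.0f%%\n",
              100 * x$prop_doc_high_actually_low))
  cat(sprintf("  documented low but calculated high: %.0f%%\n",
              100 * x$prop_doc_low_actually_high))
  invisible(x)
}
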