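#' Mutually exclusive treatment-eligibility categories
#'
#' Categories in precedence order: existing CVD (secondary prevention),
#' diabetic aged >= 40, total cholesterol >= 8 mmol/L, WHO/ISH risk
#' >= 20%, and the residual below-threshold group. The first four are
#' eligible for lipid-lowering treatment under WHO PEN; the precedence
#' order makes the categories a partition.
#'
#' @return Character vector of category labels in precedence order.
#' @export
eligibility_categories <- function() {
  c("history_of_cvd", "dm_ge40", "tc_ge8", "risk_ge20", "risk_lt20")
}

# Selected + imputed SBP/TC and chart covariates for a set of per-patient
# index dates. The risk-factor covariates (sex, age, smoking, diabetes,
# conditions) come from the patients table; SBP/TC are selected by
# direction around the index date, then imputed (SBP first - it is a TC
# model predictor).
contextual_values <- function(cohort, index, direction, model,
                              config = default_config()) {
  p <- cohort$patients
  sbp <- select_measurement(cohort$measurements, index, "sbp", direction,
                            strict = config$retrospective_strict)
  tc <- select_measurement(cohort$measurements, index, "total_cholesterol",
                           direction, strict = config$retrospective_strict)
  vals <- tibble::tibble(patient_id = index$patient_id,
                         sbp = sbp$value, tc = tc$value)
  smoker <- unname(smoking_positive(p$smoking_status, p$quit_months))
  smoker[is.na(smoker)] <- FALSE
  vals <- dplyr::left_join(
    vals,
    tibble::tibble(patient_id = p$patient_id, sex = p$sex, age = p$age,
                   smoker = smoker,
                   diabetic = p$diabetes_type != "none",
                   conditions = p$conditions),
    by = "patient_id")
  vals <- impute_sbp(vals, fill = config$sbp_fill_mmHg)
  vals <- impute_tc(vals, model)
  vals
}

#' Risk category used for treatment-eligibility assessment
#'
#' For patients with a lipid-lowering prescription, the index date is the
#' first such prescription and SBP/TC are selected retrospectively
#' (strictly before it); for never-prescribed patients, the enrolment
#' profile is used (prospective selection from the enrolment date).
#' Missing values fall through to imputation in either context.
#'
#' @param cohort An [emr_cohort()].
#' @param chart A `whoish_chart`.
#' @param model A `tc_model` from [fit_tc_model()].
#' @param config See [default_config()].
#' @return A tibble with one row per patient: `patient_id`, `risk`
#'   (ordered factor), `sbp`, `tc` (values used, after imputation),
#'   `sbp_imputed`, `tc_imputed`, `prescribed_llt`, and `context`
#'   (`treatment_eligibility` for prescribed patients, `enrolment_profile`
#'   otherwise).
#' @export
risk_for_eligibility <- function(cohort, chart, model,
                                 config = default_config()) {
  cohort <- as_emr_cohort(cohort)
  p <- cohort$patients
  llt <- cohort$prescriptions[cohort$prescriptions$drug_class == "lipid_lowering", ]
  llt <- llt[order(llt$patient_id, as.numeric(as.Date(llt$date))), ]
  first_llt <- llt[!duplicated(llt$patient_id), ]
  prescribed <- p$patient_id %in% first_llt$patient_id

  index_rx <- tibble::tibble(patient_id = first_llt$patient_id,
                             index_date = as.Date(first_llt$date))
  index_enrol <- tibble::tibble(
    patient_id = p$patient_id[!prescribed],
    index_date = as.Date(p$enrolment_date[!prescribed]))

  parts <- list()
  if (nrow(index_rx) > 0) {
    v <- contextual_values(cohort, index_rx, "retrospective", model, config)
    v$context <- "treatment_eligibility"
    parts[[length(parts) + 1]] <- v
  }
  if (nrow(index_enrol) > 0) {
    v <- contextual_values(cohort, index_enrol, "prospective", model, config)
    v$context <- "enrolment_profile"
    parts[[length(parts) + 1]] <- v
  }
  vals <- dplyr::bind_rows(parts)
  vals <- vals[match(p$patient_id, vals$patient_id), ]
  vals$risk <- calculate_risk(vals, chart)
  vals$prescribed_llt <- prescribed[match(vals$patient_id, p$patient_id)]
  vals[c("patient_id", "risk", "sbp", "tc", "sbp_imputed", "tc_imputed",
         "prescribed_llt", "context")]
}

#' Assign mutually exclusive eligibility categories
#'
#' Applies the WHO PEN eligibility rules in precedence order
#' (`history_of_cvd` -> `dm_ge40` -> `tc_ge8` -> `risk_ge20` ->
#' `risk_lt20`); the first matching rule fixes the category, so every
#' patient receives exactly one. The age used for the diabetic rule is age
#' at enrolment (the cohort stores age, not date of birth).
#'
#' @param cvd Logical: previous history of CVD (see [has_cvd_history()]).
#' @param diabetic Logical: type 1 or type 2 diabetes.
#' @param age Age in years.
#' @param tc Total cholesterol used in the same context (mmol/L, after
#'   selection/imputation).
#' @param risk Risk category from [calculate_risk()].
#' @return A tibble with columns `category` (factor over
#'   [eligibility_categories()]) and `eligible` (logical).
#' @export
#' @examples
#' assign_category(cvd = FALSE, diabetic = TRUE, age = 62, tc = 6,
#'                 risk = "<10")
assign_category <- function(cvd, diabetic, age, tc, risk) {
  risk_high <- is_high_risk(risk)
  category <- dplyr::case_when(
    cvd ~ "history_of_cvd",
    diabetic & age >= 40 ~ "dm_ge40",
    tc >= 8 ~ "tc_ge8",
    risk_high ~ "risk_ge20",
    .default = "risk_lt20"
  )
  category <- factor(category, levels = eligibility_categories())
  tibble::tibble(category = category, eligible = category != "risk_lt20")
}

#' Prescribing concordance table
#'
#' Per-eligibility-category counts, prescribing percentages and binomial
#' confidence intervals, plus the overall prescribing proportion among
#' eligible patients. Empty categories are emitted with `n = 0` and
#' undefined (NA) percentages.
#'
#' @param assignments A data frame with columns `category` (levels of
#'   [eligibility_categories()]) and `prescribed_llt` (logical).
#' @param config See [default_config()].
#' @return A tibble of class `concordance_table` with one row per
#'   category; the overall eligible summary is in attribute `overall`.
#' @export
concordance <- function(assignments, config = default_config()) {
  category <- factor(assignments$category, levels = eligibility_categories())
  rows <- lapply(eligibility_categories(), function(cat) {
    in_cat <- category == cat
    n <- sum(in_cat)
    x <- sum(assignments$prescribed_llt[in_cat])
    ci <- if (n > 0) proportion_ci(x, n, config$ci_method, config$conf_level)
          else c(lower = NA_real_, upper = NA_real_)
    tibble::tibble(
      category = cat, n = n, n_prescribed = x,
      percent_prescribed = if (n > 0) 100 * x / n else NA_real_,
      ci_lower = 100 * ci[["lower"]], ci_upper = 100 * ci[["upper"]],
      undefined = n == 0
    )
  })
  out <- dplyr::bind_rows(rows)
  elig <- out$category != "risk_lt20"
  n_el <- sum(out$n[elig]); x_el <- sum(out$n_prescribed[elig])
  ci <- if (n_el > 0) proportion_ci(x_el, n_el, config$ci_method, config$conf_level)
        else c(lower = NA_real_, upper = NA_real_)
  attr(out, "overall") <- tibble::tibble(
    n_eligible = n_el, n_prescribed = x_el,
    percent_prescribed = if (n_el > 0) 100 * x_el / n_el else NA_real_,
    ci_lower = 100 * ci[["lower"]], ci_upper = 100 * ci[["upper"]]
  )
  class(out) <- c("concordance_table", class(out))
  out
}

#' @export
print.concordance_table <- function(x, ...) {
  cat("Lipid-lowering treatment prescribing by eligibility category\n")
  NextMethod()
  ov <- attr(x, "overall")
  cat(sprintf("Overall, eligible patients prescribed: %d/%d = %.1f%% (%.1f, %.1f)\n",
              ov$n_prescribed, ov$n_eligible, ov$percent_prescribed,
              ov$ci_lower, ov$ci_upper))
  invisible(x)
}
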