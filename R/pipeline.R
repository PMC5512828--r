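#' Pipeline configuration
#'
#' Tunable constants of the analysis pipeline, with their defaults:
#' \describe{
#'   \item{sbp_fill_mmHg}{constant used to impute missing SBP (130 mmHg,
#'     a typical admission mean where SBP missingness is rare).}
#'   \item{retrospective_strict}{exclude measurements dated exactly on the
#'     index date in retrospective selection (`TRUE`).}
#'   \item{ci_method}{binomial CI method for reported proportions,
#'     `"wilson_cc"` or `"exact"`.}
#'   \item{conf_level}{confidence level for all intervals (0.95).}
#' }
#'
#' @param ... Named overrides of the defaults.
#' @return A named list.
#' @export
default_config <- function(...) {
  config <- list(
    sbp_fill_mmHg = 130,
    retrospective_strict = TRUE,
    ci_method = "wilson_cc",
    conf_level = 0.95
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(config))
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  config[names(overrides)] <- overrides
  config
}

#' Run the full risk-assessment analysis pipeline
#'
#' Executes, in order: inclusion screening; prospective measurement
#' selection at enrolment; SBP imputation, cholesterol-model fitting on
#' complete cases and TC imputation; WHO/ISH chart scoring of the whole
#' included population; the population risk profile; treatment-eligibility
#' classification (retrospective selection at first prescription for
#' treated patients) with the prescribing concordance table; and the
#' documented-versus-calculated agreement analysis. The result is
#' deterministic given the cohort, chart and configuration.
#'
#' @param cohort An [emr_cohort()].
#' @param chart A `whoish_chart` (default: the synthetic EMR-B-style
#'   chart).
#' @param config See [default_config()].
#' @return A list of class `penrisk_report`: `flow`, `population` (per
#'   stratum summary), `concordance`, `agreement`, `headline` (named
#'   proportions with CIs), `tc_model`, and a `provenance` block (counts,
#'   configuration, package version).
#' @export
run_pipeline <- function(cohort, chart = synthetic_chart(),
                         config = default_config()) {
  cohort <- as_emr_cohort(cohort)
  validate_cohort(cohort)
  report <- validate_chart(chart)
  if (nrow(report) > 0) {
    stop("invalid chart: ", nrow(report), " issue(s); first: ",
         report$issue[1], " [", report$cell[1], "]", call. = FALSE)
  }

  fc <- filter_cohort(cohort)
  inc <- fc$included
  p <- inc$patients
  n_inc <- nrow(p)
  if (n_inc == 0) stop("no patients pass inclusion screening", call. = FALSE)

  # enrolment profile: prospective selection, then imputation
  index_enrol <- tibble::tibble(patient_id = p$patient_id,
                                index_date = as.Date(p$enrolment_date))
  sbp <- select_measurement(inc$measurements, index_enrol, "sbp", "prospective")
  tc <- select_measurement(inc$measurements, index_enrol, "total_cholesterol",
                           "prospective")
  smoker <- unname(smoking_positive(p$smoking_status, p$quit_months))
  smoker[is.na(smoker)] <- FALSE
  enrol <- tibble::tibble(
    patient_id = p$patient_id, sex = p$sex, age = p$age,
    smoker = smoker,
    diabetic = p$diabetes_type != "none",
    sbp = sbp$value, tc = tc$value
  )
  n_missing_tc <- sum(is.na(enrol$tc))
  n_missing_sbp <- sum(is.na(enrol$sbp))
  enrol <- impute_sbp(enrol, fill = config$sbp_fill_mmHg)
  complete <- enrol[!enrol$sbp_imputed & !is.na(enrol$tc), ]
  model <- fit_tc_model(complete)
  enrol <- impute_tc(enrol, model)
  enrol$risk <- calculate_risk(enrol, chart)

  cvd <- has_cvd_history(p$conditions)
  stratum <- ifelse(cvd, "history_of_cvd", as.character(enrol$risk))
  population <- population_summary(p, stratum, enrol, config)

  # eligibility + prescribing concordance
  elig_risk <- risk_for_eligibility(inc, chart, model, config)
  assignments <- assign_category(cvd = cvd, diabetic = enrol$diabetic,
                                 age = p$age, tc = elig_risk$tc,
                                 risk = elig_risk$risk)
  assignments <- dplyr::bind_cols(
    tibble::tibble(patient_id = p$patient_id), assignments,
    elig_risk[c("risk", "context", "prescribed_llt")])
  conc <- concordance(assignments, config)

  # documented-score accuracy
  pairs <- documented_accuracy_pairs(inc, chart, model, config)
  agreement <- summarise_agreement(pairs, config)

  flow <- c(screened = nrow(cohort$patients), fc$tally, included = n_inc)
  ci_pct <- function(x, n) {
    ci <- proportion_ci(x, n, config$ci_method, config$conf_level)
    c(percent = 100 * x / n, lower = 100 * ci[["lower"]],
      upper = 100 * ci[["upper"]], x = x, n = n)
  }
  overall <- attr(conc, "overall")
  headline <- list(
    cvd_history = ci_pct(sum(stratum == "history_of_cvd"), n_inc),
    low_risk_lt10 = ci_pct(sum(stratum == "<10"), n_inc),
    documented = ci_pct(nrow(pairs), n_inc),
    eligible = ci_pct(overall$n_eligible, n_inc),
    eligible_via_cvd_or_dm = ci_pct(
      sum(assignments$category %in% c("history_of_cvd", "dm_ge40")),
      overall$n_eligible),
    eligible_prescribed = ci_pct(overall$n_prescribed, overall$n_eligible)
  )

  structure(list(
    flow = flow,
    population = population,
    concordance = conc,
    assignments = assignments,
    agreement = agreement,
    headline = headline,
    tc_model = model,
    provenance = list(
      n_screened = nrow(cohort$patients), n_included = n_inc,
      n_missing_tc = n_missing_tc, n_missing_sbp = n_missing_sbp,
      n_measurements = nrow(cohort$measurements),
      n_prescriptions = nrow(cohort$prescriptions),
      chart_subregion = unique(chart$subregion),
      config = config,
      package_version = as.character(utils::packageVersion("penrisk"))
    )
  ), class = "penrisk_report")
}

#' Population risk profile (per-stratum summary)
#'
#' One row per stratum (the five chart categories at enrolment, with
#' CVD-history patients reported as their own stratum regardless of chart
#' score): n, percent of total with CI, median age (IQR), percent male,
#' type 1/2 diabetes, smoking, family-history and high-waist prevalences,
#' and mean (sd) of the selected (post-imputation) SBP and TC. Quantiles
#' use the standard order-statistic definition with linear interpolation.
#' Empty strata appear with `n = 0`.
#'
#' @param patients Included patients table.
#' @param stratum Character vector of stratum labels, one per patient.
#' @param values Data frame with the per-patient `sbp` and `tc` used for
#'   scoring.
#' @param config See [default_config()].
#' @return A tibble, one row per stratum.
#' @export
population_summary <- function(patients, stratum, values,
                               config = default_config()) {
  n_total <- nrow(patients)
  levels_ <- c(risk_levels(), "history_of_cvd")
  smoker <- smoking_positive(patients$smoking_status, patients$quit_months)
  waist <- as.logical(high_waist(patients$waist_cm, patients$sex))
  rows <- lapply(levels_, function(lev) {
    in_s <- stratum == lev
    n <- sum(in_s)
    if (n == 0) {
      return(tibble::tibble(stratum = lev, n = 0L, percent = 0,
                            ci_lower = NA_real_, ci_upper = NA_real_,
                            age_median = NA_real_, age_q1 = NA_real_,
                            age_q3 = NA_real_, pct_male = NA_real_,
                            pct_t1dm = NA_real_, pct_t2dm = NA_real_,
                            pct_smoke = NA_real_, pct_fh_dm = NA_real_,
                            pct_fh_cvd = NA_real_, pct_high_waist = NA_real_,
                            sbp_mean = NA_real_, sbp_sd = NA_real_,
                            tc_mean = NA_real_, tc_sd = NA_real_))
    }
    ci <- proportion_ci(n, n_total, config$ci_method, config$conf_level)
    q <- quantile(patients$age[in_s], c(0.25, 0.5, 0.75), names = FALSE)
    tibble::tibble(
      stratum = lev, n = as.integer(n), percent = 100 * n / n_total,
      ci_lower = 100 * ci[["lower"]], ci_upper = 100 * ci[["upper"]],
      age_median = q[2], age_q1 = q[1], age_q3 = q[3],
      pct_male = 100 * mean(patients$sex[in_s] == "male"),
      pct_t1dm = 100 * mean(patients$diabetes_type[in_s] == "type1"),
      pct_t2dm = 100 * mean(patients$diabetes_type[in_s] == "type2"),
      pct_smoke = 100 * mean(smoker[in_s], na.rm = TRUE),
      pct_fh_dm = 100 * mean(patients$family_history_dm[in_s], na.rm = TRUE),
      pct_fh_cvd = 100 * mean(patients$family_history_cvd[in_s], na.rm = TRUE),
      pct_high_waist = 100 * mean(waist[in_s]),
      sbp_mean = mean(values$sbp[in_s]), sbp_sd = sd(values$sbp[in_s]),
      tc_mean = mean(values$tc[in_s]), tc_sd = sd(values$tc[in_s])
    )
  })
  dplyr::bind_rows(rows)
}

#' @export
print.penrisk_report <- function(x, ...) {
  cat("== Total CVD risk assessment report ==\n")
  cat("Flow: screened", x$flow[["screened"]],
      "| excluded <18:", x$flow[["excluded_under18"]],
      "| excluded 18-39 no risk factor:", x$flow[["excluded_under40_no_risk"]],
      "| included:", x$flow[["included"]], "\n\n")
  cat("Population by risk stratum:\n")
  print(x$population[c("stratum", "n", "percent", "age_median", "pct_male",
                       "sbp_mean", "tc_mean")], n = Inf)
  cat("\n")
  print(x$concordance)
  cat("\n")
  print(x$agreement)
  cat("\nHeadline proportions (value [95% CI]):\n")
  for (nm in names(x$headline)) {
    h <- x$headline[[nm]]
    cat(sprintf("  %-24s %5.1f%% [%.1f, %.1f]  (%d/%d)\n", nm,
                h[["percent"]], h[["lower"]], h[["upper"]],
                h[["x"]], h[["n"]]))
  }
  invisible(x)
}

#' Write a report to disk
#'
#' Persists the report as machine-readable files in a directory:
#' `population.csv`, `concordance.csv`, `assignments.csv`,
#' `agreement_table.csv`, `agreement_binary.csv` and `report.json`
#' (flow, headline proportions, kappa variants, provenance).
#'
#' @param report A `penrisk_report` from [run_pipeline()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_csv(report$population, file.path(dir, "population.csv"), na = "")
  readr::write_csv(tibble::as_tibble(report$concordance),
                   file.path(dir, "concordance.csv"), na = "")
  readr::write_csv(report$assignments, file.path(dir, "assignments.csv"), na = "")
  write_tab <- function(tab, path) {
    df <- as.data.frame.matrix(tab)
    df <- cbind(documented = rownames(tab), df)
    readr::write_csv(tibble::as_tibble(df), path)
  }
  write_tab(report$agreement$table, file.path(dir, "agreement_table.csv"))
  write_tab(report$agreement$table_binary, file.path(dir, "agreement_binary.csv"))
  json <- list(
    flow = as.list(report$flow),
    headline = lapply(report$headline, as.list),
    kappa = list(binary = report$agreement$kappa_binary,
                 six_level_matched = report$agreement$kappa_matched),
    prop_correct = report$agreement$prop_correct,
    tc_model = as.list(report$tc_model$coefficients),
    provenance = report$provenance
  )
  jsonlite::write_json(json, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
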