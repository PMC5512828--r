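#' Default synthetic cohort specification
#'
#' A [cohort_spec] populated with the marginals of the calibration cohort
#' (see [reference_tables()]): stratum mix and per-stratum age, sex,
#' diabetes, smoking, family-history, waist, SBP and TC distributions;
#' missingness of 576/2907 (TC) and 15/2907 (SBP); a documentation
#' probability of 680/2907; a documentation error kernel obtained by
#' column-normalising the reference agreement table (so the error process
#' reproduces the observed under-calling asymmetry); and per-category
#' prescribing probabilities.
#'
#' @param n_patients Number of patients to simulate (default: the
#'   calibration cohort size, 2907).
#' @param seed Default random seed carried in the spec (can be overridden
#'   in [generate_cohort()]).
#' @return A `cohort_spec` list.
#' @export
#' @examples
#' spec <- default_spec()
#' spec$prescribing[["history_of_cvd"]]  # 0.706
default_spec <- function(n_patients = 2907, seed = 20151101) {
  ref <- reference_tables()
  st <- ref$strata
  kernel <- apply(ref$agreement, 2, function(col) col / sum(col))
  kernel <- t(kernel)  # rows: calculated (truth) level; cols: documented level
  spec <- list(
    n_patients = n_patients,
    seed = seed,
    strata = st,
    category_mix = setNames(st$n / sum(st$n), st$stratum),
    missing_tc = 576 / 2907,
    missing_sbp = 15 / 2907,
    p_documented = 680 / 2907,
    doc_kernel = kernel,
    prescribing = setNames(ref$prescribing$pct_prescribed / 100,
                           ref$prescribing$category),
    sbp_bounds = c(70, 260),
    tc_bounds = c(2, 15),
    enrol_window = as.Date(c("2014-12-15", "2015-11-01")),
    p_waist_missing = 0.03,
    p_other_rx = 0.4
  )
  class(spec) <- "cohort_spec"
  validate_spec(spec)
  spec
}

#' Validate a cohort specification
#'
#' Field-level checks: probabilities in \[0, 1\], a stratum mix summing to
#' one, positive standard deviations, a row-stochastic documentation error
#' kernel, and prescribing probabilities for every eligibility category.
#'
#' @param spec A `cohort_spec`.
#' @return Invisibly, the spec; errors name the offending field.
#' @export
validate_spec <- function(spec) {
  fail <- function(field, why) {
    stop("invalid cohort spec: field '", field, "' ", why, call. = FALSE)
  }
  if (is.null(spec$n_patients) || spec$n_patients < 0) fail("n_patients", "must be >= 0")
  if (abs(sum(spec$category_mix) - 1) > 1e-8) fail("category_mix", "must sum to 1")
  probs <- c(spec$missing_tc, spec$missing_sbp, spec$p_documented,
             spec$prescribing, spec$category_mix, spec$p_waist_missing,
             spec$p_other_rx)
  if (any(probs < 0 | probs > 1)) fail("probabilities", "must lie in [0, 1]")
  st <- spec$strata
  if (any(st$sbp_sd <= 0) || any(st$tc_sd <= 0)) fail("strata", "sds must be > 0")
  if (any(st$age_q1 >= st$age_q3)) fail("strata", "age quartiles must be ordered")
  if (!setequal(names(spec$prescribing), eligibility_categories())) {
    fail("prescribing", "must cover every eligibility category")
  }
  k <- spec$doc_kernel
  if (!all(dim(k) == c(6, 5)) || any(abs(rowSums(k) - 1) > 1e-8) || any(k < 0)) {
    fail("doc_kernel", "must be a row-stochastic 6 x 5 matrix")
  }
  invisible(spec)
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("<cohort_spec>", x$n_patients, "patients;",
      "strata:", paste(names(x$category_mix), collapse = ", "), "\n")
  invisible(x)
}

#' Generate a synthetic EMR cohort
#'
#' Draws a cohort with the statistical structure described by the spec.
#' Each patient gets a latent risk stratum, stratum-conditional
#' demographics and risk factors (conditionally independent given the
#' stratum), baseline SBP/TC measurements shortly after enrolment (subject
#' to the spec's missingness), follow-up measurements for a subset, a
#' documented risk score with the spec's probability and error kernel, and
#' prescriptions drawn from the patient's true eligibility category. The
#' generator's latent truths are attached for parameter-recovery testing
#' and retrieved with [truth_table()]. The same spec and seed always yield
#' an identical cohort.
#'
#' @param spec A `cohort_spec`, e.g. [default_spec()].
#' @param seed Integer seed (defaults to the spec's).
#' @return An [emr_cohort()] with a `truth` attribute.
#' @export
generate_cohort <- function(spec, seed = spec$seed) {
  validate_spec(spec)
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(spec$n_patients)
  st <- spec$strata
  s <- sample.int(nrow(st), n, replace = TRUE, prob = spec$category_mix)
  stratum <- st$stratum[s]
  pr <- function(col) st[[col]][s] / 100

  sex <- ifelse(runif(n) < pr("pct_male"), "male", "female")
  sdlog <- (log(st$age_q3) - log(st$age_q1)) / (2 * qnorm(0.75))
  age <- as.integer(pmin(95, pmax(18, round(
    rlnorm(n, meanlog = log(st$age_median)[s], sdlog = sdlog[s])))))

  u_dm <- runif(n)
  diabetes_type <- ifelse(u_dm < pr("pct_t1dm"), "type1",
                   ifelse(u_dm < pr("pct_t1dm") + pr("pct_t2dm"), "type2", "none"))
  u_sm <- runif(n)
  smoking_status <- ifelse(u_sm < pr("pct_smoke"), "current",
                    ifelse(u_sm < pr("pct_smoke") + 0.05, "quit", "never"))
  quit_months <- ifelse(smoking_status == "quit",
                        sample(12:240, n, replace = TRUE), NA_integer_)
  family_history_cvd <- runif(n) < pr("pct_fh_cvd")
  family_history_dm <- runif(n) < pr("pct_fh_dm")

  thr <- ifelse(sex == "female", 90, 100)
  waist_high <- runif(n) < pr("pct_high_waist")
  waist_cm <- round(ifelse(waist_high, runif(n, thr, thr + 35),
                           runif(n, 60, thr - 1)), 1)
  waist_cm[runif(n) < spec$p_waist_missing] <- NA_real_

  window_days <- as.integer(diff(spec$enrol_window))
  enrolment_date <- spec$enrol_window[1] +
    sample.int(window_days + 1L, n, replace = TRUE) - 1L

  clamp <- function(x, b) pmin(b[2], pmax(b[1], x))
  sbp_true <- clamp(rnorm(n, st$sbp_mean[s], st$sbp_sd[s]), spec$sbp_bounds)
  tc_true <- clamp(rnorm(n, st$tc_mean[s], st$tc_sd[s]), spec$tc_bounds)

  is_cvd <- stratum == "history_of_cvd"
  conditions <- vector("list", n)
  cvd_pick <- sample(cvd_condition_codes(), n, replace = TRUE)
  extra_htn <- runif(n) < 0.4
  for (i in seq_len(n)) {
    cond <- character()
    if (is_cvd[i]) cond <- cvd_pick[i]
    if (diabetes_type[i] != "none") cond <- c(cond, "diabetes")
    if (extra_htn[i]) cond <- c(cond, "hypertension")
    conditions[[i]] <- cond
  }

  patient_id <- sprintf("P%05d", seq_len(n))
  patients <- tibble::tibble(
    patient_id, sex, age, enrolment_date, conditions,
    family_history_cvd, family_history_dm, diabetes_type,
    smoking_status, quit_months, waist_cm
  )

  # baseline measurements (missing with the spec's probabilities) and
  # follow-up measurements for a subset of patients
  sbp_miss <- runif(n) < spec$missing_sbp
  tc_miss <- runif(n) < spec$missing_tc
  meas <- list(
    tibble::tibble(patient_id,
                   date = enrolment_date + sample(0:14, n, replace = TRUE),
                   kind = "sbp",
                   value = ifelse(sbp_miss, NA_real_, round(sbp_true, 1))),
    tibble::tibble(patient_id,
                   date = enrolment_date + sample(0:30, n, replace = TRUE),
                   kind = "total_cholesterol",
                   value = ifelse(tc_miss, NA_real_, round(tc_true, 2)))
  )
  fu_sbp <- runif(n) < 0.6
  if (any(fu_sbp)) {
    m <- sum(fu_sbp)
    meas[[3]] <- tibble::tibble(
      patient_id = patient_id[fu_sbp],
      date = enrolment_date[fu_sbp] + sample(45:180, m, replace = TRUE),
      kind = "sbp",
      value = round(clamp(rnorm(m, st$sbp_mean[s][fu_sbp], st$sbp_sd[s][fu_sbp]),
                          spec$sbp_bounds), 1))
  }
  fu_tc <- runif(n) < 0.3
  if (any(fu_tc)) {
    m <- sum(fu_tc)
    meas[[length(meas) + 1]] <- tibble::tibble(
      patient_id = patient_id[fu_tc],
      date = enrolment_date[fu_tc] + sample(45:180, m, replace = TRUE),
      kind = "total_cholesterol",
      value = round(clamp(rnorm(m, st$tc_mean[s][fu_tc], st$tc_sd[s][fu_tc]),
                          spec$tc_bounds), 2))
  }
  measurements <- dplyr::bind_rows(meas)

  truth_category <- ifelse(is_cvd, "history_of_cvd",
                    ifelse(diabetes_type != "none" & age >= 40, "dm_ge40",
                    ifelse(tc_true >= 8, "tc_ge8",
                    ifelse(stratum %in% c("20-<30", "30-<40", ">=40"),
                           "risk_ge20", "risk_lt20"))))
  prescribed <- runif(n) < unname(spec$prescribing[truth_category])
  rx <- list()
  if (any(prescribed)) {
    m <- sum(prescribed)
    rx[[1]] <- tibble::tibble(
      patient_id = patient_id[prescribed],
      date = enrolment_date[prescribed] + sample(31:180, m, replace = TRUE),
      drug_class = "lipid_lowering")
  }
  other <- runif(n) < spec$p_other_rx
  if (any(other)) {
    m <- sum(other)
    rx[[length(rx) + 1]] <- tibble::tibble(
      patient_id = patient_id[other],
      date = enrolment_date[other] + sample(0:60, m, replace = TRUE),
      drug_class = "other")
  }
  prescriptions <- if (length(rx) > 0) dplyr::bind_rows(rx) else prescriptions_template()

  documented <- runif(n) < spec$p_documented
  kernel_row <- ifelse(is_cvd, "history_of_cvd", stratum)
  doc_category <- rep(NA_character_, n)
  for (lev in rownames(spec$doc_kernel)) {
    pick <- documented & kernel_row == lev
    if (any(pick)) {
      doc_category[pick] <- sample(colnames(spec$doc_kernel), sum(pick),
                                   replace = TRUE, prob = spec$doc_kernel[lev, ])
    }
  }
  documented_scores <- tibble::tibble(
    patient_id = patient_id[documented],
    date = enrolment_date[documented] + sample(40:200, sum(documented),
                                               replace = TRUE),
    category = doc_category[documented])

  doc_error <- ifelse(!documented, NA,
               ifelse(is_cvd, !is_high_risk(doc_category),
                      doc_category != stratum))

  cohort <- emr_cohort(patients, measurements, prescriptions, documented_scores)
  attr(cohort, "truth") <- tibble::tibble(
    patient_id, stratum, truth_category,
    prescribed_llt = prescribed, documented,
    doc_category, doc_error,
    sbp_true = sbp_true, tc_true = tc_true
  )
  cohort
}

#' Ground-truth labels of a synthetic cohort
#'
#' Returns the generator's latent truths - true risk stratum, true
#' eligibility category, prescription and documentation indicators, the
#' documentation-error indicator and the pre-missingness SBP/TC values -
#' for parameter-recovery tests.
#'
#' @param cohort A cohort produced by [generate_cohort()].
#' @return A tibble, one row per patient.
#' @export
truth_table <- function(cohort) {
  truth <- attr(cohort, "truth")
  if (is.null(truth)) {
    stop("cohort carries no ground truth (not produced by generate_cohort)",
         call. = FALSE)
  }
  truth
}
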