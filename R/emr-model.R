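#' Condition code vocabulary
#'
#' Controlled vocabulary of condition codes understood by the package.
#' `cvd_condition_codes()` is the subset that counts as a previous history
#' of CVD: angina (stable or unstable), myocardial infarction, angioplasty,
#' congestive heart failure, peripheral vascular disease, any other CVD
#' condition (e.g. atrial fibrillation), or a documented cardiovascular or
#' cerebrovascular complication. The remaining codes cover the chronic
#' conditions such clinics typically enrol for and carry no CVD-history
#' meaning.
#'
#' @return Character vector of condition codes.
#' @export
condition_vocabulary <- function() {
  c(cvd_condition_codes(), "hypertension", "diabetes", "copd", "asthma")
}

#' @rdname condition_vocabulary
#' @export
cvd_condition_codes <- function() {
  c("stable_angina", "unstable_angina", "myocardial_infarction",
    "angioplasty", "congestive_heart_failure", "peripheral_vascular_disease",
    "other_cvd", "cv_or_cerebrovascular_complication")
}

#' Previous history of CVD
#'
#' A patient is coded CVD-positive if any of their condition codes is a CVD
#' code (see [cvd_condition_codes()]). Codes outside the vocabulary are
#' ignored with a warning so that cohorts carrying extra source codes still
#' screen cleanly.
#'
#' @param conditions A character vector of condition codes (one patient) or
#'   a list of such vectors (one element per patient).
#' @return Logical, one value per patient.
#' @export
#' @examples
#' has_cvd_history(c("myocardial_infarction", "hypertension"))
#' has_cvd_history(list(character(), "other_cvd"))
has_cvd_history <- function(conditions) {
  if (!is.list(conditions)) conditions <- list(conditions)
  all_codes <- unique(unlist(conditions, use.names = FALSE))
  unknown <- setdiff(all_codes, condition_vocabulary())
  if (length(unknown) > 0) {
    warning("ignoring unknown condition code(s): ",
            paste(unknown, collapse = ", "), call. = FALSE)
  }
  vapply(conditions, function(x) any(x %in% cvd_condition_codes()), logical(1))
}

#' Smoking coded positive
#'
#' Positive if the patient currently smokes or quit within the previous 12
#' months (the WHO PEN convention used for both inclusion screening and
#' chart scoring).
#'
#' @param status Character vector over `"current"`, `"quit"`, `"never"`.
#' @param quit_months Integer months since quitting; only consulted where
#'   `status == "quit"` (missing months are treated as a non-recent quit).
#' @return Logical vector.
#' @export
#' @examples
#' smoking_positive(c("current", "quit", "quit", "never"), c(NA, 6, 24, NA))
smoking_positive <- function(status, quit_months = NULL) {
  status <- as.character(status)
  bad <- !is.na(status) & !status %in% c("current", "quit", "never")
  if (any(bad)) {
    stop("invalid smoking status: ", paste(unique(status[bad]), collapse = ", "),
         call. = FALSE)
  }
  if (is.null(quit_months)) quit_months <- rep(NA_real_, length(status))
  out <- status == "current" |
    (status == "quit" & !is.na(quit_months) & quit_months < 12)
  out[is.na(status)] <- NA
  out
}

#' High waist circumference
#'
#' Sex-specific thresholds, inclusive: >= 90 cm in women, >= 100 cm in men.
#' A missing waist measurement returns `FALSE` (the patient cannot qualify
#' for inclusion through this criterion) and is flagged in the
#' `"unassessable"` attribute of the result.
#'
#' @param waist_cm Numeric waist circumference in centimetres (NA allowed).
#' @param sex Character vector, `"male"` or `"female"`.
#' @return Logical vector with attribute `unassessable` (logical, `TRUE`
#'   where the waist value was absent).
#' @export
#' @examples
#' high_waist(c(90, 99, 100, NA), c("female", "male", "male", "female"))
high_waist <- function(waist_cm, sex) {
  sex <- check_sex(sex)
  threshold <- ifelse(sex == "female", 90, 100)
  out <- !is.na(waist_cm) & waist_cm >= threshold
  attr(out, "unassessable") <- is.na(waist_cm)
  out
}

check_sex <- function(sex) {
  sex <- as.character(sex)
  bad <- !is.na(sex) & !sex %in% c("male", "female")
  if (any(bad)) {
    stop("invalid sex value(s): ", paste(unique(sex[bad]), collapse = ", "),
         call. = FALSE)
  }
  sex
}

#' WHO PEN derived inclusion screening
#'
#' All patients aged 40 or over are included. Adults (18-39) are included
#' only with at least one qualifying risk factor: smoking (current or quit
#' < 12 months), diabetes (type 1 or 2), a family history of premature CVD
#' or of diabetes in a first- or second-degree relative, or a high waist
#' circumference. Patients under 18 are never included. Missing risk-factor
#' fields are treated as absent risk factors.
#'
#' @param patients A patients table (see [emr_cohort()]) or any data frame
#'   with columns `age`, `sex`, `diabetes_type`, `smoking_status`,
#'   `quit_months`, `family_history_cvd`, `family_history_dm`, `waist_cm`.
#' @return Logical vector, one element per row.
#' @export
meets_inclusion <- function(patients) {
  age <- patients$age
  smoker <- smoking_positive(patients$smoking_status, patients$quit_months)
  smoker[is.na(smoker)] <- FALSE
  diabetic <- !is.na(patients$diabetes_type) & patients$diabetes_type != "none"
  fh_cvd <- !is.na(patients$family_history_cvd) & patients$family_history_cvd
  fh_dm <- !is.na(patients$family_history_dm) & patients$family_history_dm
  waist <- as.logical(high_waist(patients$waist_cm, patients$sex))
  risk_factor <- smoker | diabetic | fh_cvd | fh_dm | waist
  age >= 40 | (age >= 18 & risk_factor)
}

#' Screen a cohort for inclusion
#'
#' Partitions a cohort into the included analysis population and the two
#' exclusion tallies: patients under 18, and 18-39-year-olds without a
#' qualifying risk factor. All relational tables (measurements,
#' prescriptions, documented scores) are subset to the included patients.
#'
#' @param cohort An [emr_cohort()].
#' @return A list with elements `included` (an `emr_cohort`) and `tally`
#'   (named integer vector: `excluded_under18`, `excluded_under40_no_risk`).
#' @export
filter_cohort <- function(cohort) {
  cohort <- as_emr_cohort(cohort)
  p <- cohort$patients
  keep <- meets_inclusion(p)
  under18 <- p$age < 18
  tally <- c(
    excluded_under18 = sum(under18),
    excluded_under40_no_risk = sum(!keep & !under18)
  )
  list(included = subset_cohort(cohort, p$patient_id[keep]), tally = tally)
}

# ---- cohort container ------------------------------------------------------

patients_template <- function() {
  tibble::tibble(
    patient_id = character(), sex = character(), age = integer(),
    enrolment_date = as.Date(character()), conditions = list(),
    family_history_cvd = logical(), family_history_dm = logical(),
    diabetes_type = character(), smoking_status = character(),
    quit_months = integer(), waist_cm = double()
  )
}

measurements_template <- function() {
  tibble::tibble(patient_id = character(), date = as.Date(character()),
                 kind = character(), value = double())
}

prescriptions_template <- function() {
  tibble::tibble(patient_id = character(), date = as.Date(character()),
                 drug_class = character())
}

documented_scores_template <- function() {
  tibble::tibble(patient_id = character(), date = as.Date(character()),
                 category = character())
}

#' EMR cohort container
#'
#' A relational container for a clinic EMR extract: a patients table
#' (demographics, condition codes, risk factors), visit-stamped
#' measurements (SBP in mmHg, total cholesterol in mmol/L; `NA` value =
#' recorded-but-missing), prescriptions (`lipid_lowering` vs `other`), and
#' clinician-documented risk scores. Measurement and prescription dates may
#' legitimately predate enrolment (retrospective records).
#'
#' @param patients Data frame with columns `patient_id`, `sex`
#'   (male/female), `age` (whole years at enrolment), `enrolment_date`,
#'   `conditions` (list of code vectors, or `;`-separated strings),
#'   `family_history_cvd`, `family_history_dm`, `diabetes_type`
#'   (none/type1/type2), `smoking_status` (current/quit/never),
#'   `quit_months`, `waist_cm`.
#' @param measurements Data frame with `patient_id`, `date`, `kind`
#'   (`sbp`/`total_cholesterol`), `value`.
#' @param prescriptions Data frame with `patient_id`, `date`, `drug_class`.
#' @param documented_scores Data frame with `patient_id`, `date`,
#'   `category` (a label from [risk_levels()]).
#' @return An object of class `emr_cohort`.
#' @export
emr_cohort <- function(patients,
                       measurements = measurements_template(),
                       prescriptions = prescriptions_template(),
                       documented_scores = documented_scores_template()) {
  patients <- tibble::as_tibble(patients)
  if ("conditions" %in% names(patients) && is.character(patients$conditions)) {
    patients$conditions <- split_condition_strings(patients$conditions)
  }
  if (!"conditions" %in% names(patients)) {
    patients$conditions <- replicate(nrow(patients), character(), simplify = FALSE)
  }
  out <- structure(
    list(
      patients = patients,
      measurements = tibble::as_tibble(measurements),
      prescriptions = tibble::as_tibble(prescriptions),
      documented_scores = tibble::as_tibble(documented_scores)
    ),
    class = "emr_cohort"
  )
  validate_cohort(out)
  out
}

split_condition_strings <- function(x) {
  lapply(strsplit(ifelse(is.na(x), "", x), ";", fixed = TRUE),
         function(v) trimws(v[nzchar(trimws(v))]))
}

as_emr_cohort <- function(x) {
  if (inherits(x, "emr_cohort")) x else stop("not an emr_cohort", call. = FALSE)
}

#' Validate an EMR cohort
#'
#' Checks the relational schema and field-level invariants: unique patient
#' ids, valid sex/diabetes/smoking codes, non-negative ages, valid dates,
#' strictly positive non-missing measurement values, known measurement
#' kinds and drug classes, valid documented risk categories, and referential
#' integrity of every child table. Errors on the first violation.
#'
#' @param cohort An `emr_cohort`.
#' @return Invisibly, the cohort.
#' @export
validate_cohort <- function(cohort) {
  p <- cohort$patients
  req <- setdiff(names(patients_template()), "conditions")
  missing_cols <- setdiff(req, names(p))
  if (length(missing_cols) > 0) {
    stop("patients table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(p$patient_id)) stop("duplicate patient_id", call. = FALSE)
  check_sex(p$sex)
  if (any(!is.na(p$age) & p$age < 0)) stop("negative age", call. = FALSE)
  if (any(is.na(p$age))) stop("missing age", call. = FALSE)
  if (any(is.na(as.Date(p$enrolment_date)))) {
    stop("invalid enrolment_date", call. = FALSE)
  }
  bad_dm <- !p$diabetes_type %in% c("none", "type1", "type2")
  if (any(bad_dm)) {
    stop("invalid diabetes_type: ",
         paste(unique(p$diabetes_type[bad_dm]), collapse = ", "), call. = FALSE)
  }
  smoking_positive(p$smoking_status, p$quit_months)  # validates codes
  m <- cohort$measurements
  if (nrow(m) > 0) {
    if (any(!m$kind %in% c("sbp", "total_cholesterol"))) {
      stop("invalid measurement kind", call. = FALSE)
    }
    if (any(!is.na(m$value) & m$value <= 0)) {
      stop("non-positive measurement value", call. = FALSE)
    }
    if (any(is.na(as.Date(m$date)))) stop("invalid measurement date", call. = FALSE)
  }
  rx <- cohort$prescriptions
  if (nrow(rx) > 0 && any(!rx$drug_class %in% c("lipid_lowering", "other"))) {
    stop("invalid drug_class", call. = FALSE)
  }
  d <- cohort$documented_scores
  if (nrow(d) > 0) as_risk_category(d$category)
  for (tab in c("measurements", "prescriptions", "documented_scores")) {
    orphan <- setdiff(cohort[[tab]]$patient_id, p$patient_id)
    if (length(orphan) > 0) {
      stop(tab, " refers to unknown patient_id: ",
           paste(head(orphan, 5), collapse = ", "), call. = FALSE)
    }
  }
  invisible(cohort)
}

subset_cohort <- function(cohort, ids) {
  out <- cohort
  out$patients <- cohort$patients[cohort$patients$patient_id %in% ids, ]
  for (tab in c("measurements", "prescriptions", "documented_scores")) {
    out[[tab]] <- cohort[[tab]][cohort[[tab]]$patient_id %in% ids, ]
  }
  out
}

#' @export
print.emr_cohort <- function(x, ...) {
  cat("<emr_cohort> ", nrow(x$patients), " patients, ",
      nrow(x$measurements), " measurements, ",
      nrow(x$prescriptions), " prescriptions, ",
      nrow(x$documented_scores), " documented risk scores\n", sep = "")
  invisible(x)
}

# ---- delimited-file interface ---------------------------------------------

#' Read and write cohorts as delimited files
#'
#' A cohort is exchanged as four UTF-8 CSV files with header rows in one
#' directory: `patients.csv`, `measurements.csv`, `prescriptions.csv` and
#' `documented_scores.csv`. Dates are ISO-8601 (`YYYY-MM-DD`); missing
#' values are empty fields; the `conditions` column holds `;`-separated
#' vocabulary codes. The documented-scores file is optional on read.
#'
#' @param dir Directory containing (or to receive) the CSV files.
#' @return `read_cohort()` returns an [emr_cohort()]; `write_cohort()`
#'   invisibly returns the directory path.
#' @export
read_cohort <- function(dir) {
  path <- function(f) file.path(dir, f)
  patients <- readr::read_csv(path("patients.csv"), show_col_types = FALSE,
    col_types = readr::cols(
      patient_id = "c", sex = "c", age = "i", enrolment_date = "D",
      conditions = "c", family_history_cvd = "l", family_history_dm = "l",
      diabetes_type = "c", smoking_status = "c", quit_months = "i",
      waist_cm = "d"))
  measurements <- readr::read_csv(path("measurements.csv"),
    show_col_types = FALSE,
    col_types = readr::cols(patient_id = "c", date = "D", kind = "c",
                            value = "d"))
  prescriptions <- readr::read_csv(path("prescriptions.csv"),
    show_col_types = FALSE,
    col_types = readr::cols(patient_id = "c", date = "D", drug_class = "c"))
  ds_path <- path("documented_scores.csv")
  documented <- if (file.exists(ds_path)) {
    readr::read_csv(ds_path, show_col_types = FALSE,
      col_types = readr::cols(patient_id = "c", date = "D", category = "c"))
  } else {
    documented_scores_template()
  }
  emr_cohort(patients, measurements, prescriptions, documented)
}

#' @rdname read_cohort
#' @param cohort An [emr_cohort()].
#' @export
write_cohort <- function(cohort, dir) {
  cohort <- as_emr_cohort(cohort)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p <- cohort$patients
  p$conditions <- vapply(p$conditions, paste, character(1), collapse = ";")
  readr::write_csv(p, file.path(dir, "patients.csv"), na = "")
  readr::write_csv(cohort$measurements, file.path(dir, "measurements.csv"), na = "")
  readr::write_csv(cohort$prescriptions, file.path(dir, "prescriptions.csv"), na = "")
  readr::write_csv(cohort$documented_scores,
                   file.path(dir, "documented_scores.csv"), na = "")
  invisible(dir)
}

#' Map source condition strings to vocabulary codes
#'
#' EMR extracts carry free-text or site-specific condition labels; a YAML
#' mapping file translates them to the package vocabulary. Strings already
#' in the vocabulary pass through unchanged; unmapped strings are dropped
#' with a warning.
#'
#' @param path Path to a YAML file of `source string: vocabulary code`
#'   pairs.
#' @return `read_condition_map()` returns a named character vector;
#'   `map_conditions()` returns the translated vector (or list).
#' @export
read_condition_map <- function(path) {
  map <- unlist(yaml::read_yaml(path))
  bad <- !map %in% condition_vocabulary()
  if (any(bad)) {
    stop("mapping targets outside the vocabulary: ",
         paste(unique(map[bad]), collapse = ", "), call. = FALSE)
  }
  map
}

#' @rdname read_condition_map
#' @param x Character vector of source condition strings, or a list of such
#'   vectors (one per patient).
#' @param map Named character vector from [read_condition_map()].
#' @export
map_conditions <- function(x, map) {
  if (is.list(x)) return(lapply(x, map_conditions, map = map))
  mapped <- ifelse(x %in% names(map), unname(map[x]),
                   ifelse(x %in% condition_vocabulary(), x, NA_character_))
  if (anyNA(mapped)) {
    warning("dropping unmapped condition string(s): ",
            paste(unique(x[is.na(mapped)]), collapse = ", "), call. = FALSE)
  }
  mapped[!is.na(mapped)]
}
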