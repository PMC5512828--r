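# Shared fixtures: all built in code at test time.

# A patients row with sensible defaults, overridable per field.
make_patient <- function(patient_id = "P1", sex = "female", age = 55L,
                         enrolment_date = as.Date("2015-01-01"),
                         conditions = list(character()),
                         family_history_cvd = FALSE, family_history_dm = FALSE,
                         diabetes_type = "none", smoking_status = "never",
                         quit_months = NA_integer_, waist_cm = 80) {
  tibble::tibble(patient_id, sex, age = as.integer(age), enrolment_date,
                 conditions, family_history_cvd, family_history_dm,
                 diabetes_type, smoking_status,
                 quit_months = as.integer(quit_months), waist_cm)
}

make_measurements <- function(patient_id, dates, kind, values) {
  tibble::tibble(patient_id = patient_id, date = as.Date(dates), kind = kind,
                 value = values)
}

# A chart whose 640 cells all carry one category.
constant_chart <- function(category = "<10", subregion = "TEST") {
  chart <- synthetic_chart(subregion)
  chart$category <- category
  chart
}

# Invert a chart cell to concrete risk-factor values that land in it.
values_for_cell <- function(cell) {
  tibble::tibble(
    sex = cell$sex,
    age = c(`40` = 45, `50` = 55, `60` = 65, `70` = 75)[as.character(cell$age_band)],
    smoker = cell$smoker, diabetic = cell$diabetic,
    sbp = c("<140" = 130, "140-159" = 150, "160-179" = 170, ">=180" = 190)[cell$sbp_band],
    tc = c("<5" = 4.5, "5-<6" = 5.5, "6-<7" = 6.5, "7-<8" = 7.5, ">=8" = 8.5)[cell$tc_band]
  )
}

# Concrete (sbp, tc, age, ...) values guaranteed to score as `category`
# under `chart`.
values_for_category <- function(chart, category) {
  hit <- chart[chart$category == category, ][1, ]
  stopifnot(!is.na(hit$category))
  values_for_cell(hit)
}

# A small, well-conditioned cholesterol model for tests that only need
# some fitted model (not its particular coefficients).
toy_tc_model <- function() {
  set.seed(915)
  d <- tibble::tibble(
    age = sample(30:80, 40, TRUE),
    sex = sample(c("male", "female"), 40, TRUE),
    sbp = runif(40, 100, 200))
  d$tc <- 2 + 0.03 * d$age + 0.4 * (d$sex == "female") + 0.01 * d$sbp
  fit_tc_model(d)
}

# Random small cohort exercising all screening branches.
random_cohort_patients <- function(n) {
  tibble::tibble(
    patient_id = sprintf("R%04d", seq_len(n)),
    sex = sample(c("male", "female"), n, TRUE),
    age = as.integer(sample(10:90, n, TRUE)),
    enrolment_date = as.Date("2015-01-01") + sample(0:300, n, TRUE),
    conditions = replicate(n, character(), simplify = FALSE),
    family_history_cvd = sample(c(TRUE, FALSE), n, TRUE),
    family_history_dm = sample(c(TRUE, FALSE), n, TRUE),
    diabetes_type = sample(c("none", "type1", "type2"), n, TRUE),
    smoking_status = sample(c("current", "quit", "never"), n, TRUE),
    quit_months = as.integer(sample(c(NA, 3L, 36L), n, TRUE)),
    waist_cm = ifelse(runif(n) < 0.1, NA, round(runif(n, 60, 130)))
  )
}
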