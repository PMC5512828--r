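#' Reference summary tables from the calibration cohort
#'
#' Published summary counts from the refugee primary-care NCD cohort that
#' the default synthetic generator emulates (an Eastern Mediterranean
#' outpatient programme applying WHO PEN rules with the WHO/ISH EMR-B
#' charts). These printed aggregates are the only available description of
#' that population - the patient-level database is not deposited - and
#' they serve two roles: calibration targets for [default_spec()], and
#' inputs for re-deriving the published headline proportions.
#'
#' @return A list of tibbles/matrices:
#' \describe{
#'   \item{flow}{screening flow counts: screened, excluded under-18,
#'     excluded 18-39 without risk factors, included, and the missingness
#'     and documentation counts within the included population.}
#'   \item{strata}{per-stratum population summary (strata: the five chart
#'     categories at enrolment plus `history_of_cvd`): n, median age with
#'     quartiles, percent male, diabetes/smoking/family-history/waist
#'     prevalences, mean (sd) SBP and TC.}
#'   \item{prescribing}{per-eligibility-category totals and percent
#'     prescribed lipid-lowering treatment.}
#'   \item{agreement}{5 x 6 documented-by-calculated risk cross-tab.}
#' }
#' @export
reference_tables <- function() {
  strata <- tibble::tibble(
    stratum = c("<10", "10-<20", "20-<30", "30-<40", ">=40", "history_of_cvd"),
    n = c(1650L, 325L, 139L, 70L, 115L, 608L),
    age_median = c(50, 64, 66, 64, 66, 61),
    age_q1 = c(42, 60, 61, 61.25, 62, 53),
    age_q3 = c(57, 71, 72.5, 71, 71, 68),
    pct_male = c(33.8, 41.2, 41.7, 34.3, 40.9, 53.5),
    pct_t1dm = c(2.4, 0.3, 0.7, 0.0, 0.9, 0.2),
    pct_t2dm = c(42.5, 63.1, 64.7, 80.0, 80.0, 52.3),
    pct_smoke = c(23.7, 19.7, 32.4, 28.6, 28.7, 31.2),
    sbp_mean = c(124.39, 139.74, 146.58, 156.07, 171.64, 129.03),
    sbp_sd = c(17.60, 18.62, 20.95, 15.39, 20.47, 22.96),
    tc_mean = c(5.16, 5.18, 5.41, 5.64, 6.28, 4.74),
    tc_sd = c(0.96, 1.13, 1.61, 1.25, 1.59, 1.11),
    pct_fh_dm = c(69.0, 65.2, 48.9, 65.7, 63.5, 62.5),
    pct_fh_cvd = c(39.2, 25.8, 29.5, 21.4, 29.6, 42.3),
    pct_high_waist = c(79.5, 79.7, 73.4, 85.7, 83.5, 72.7)
  )
  prescribing <- tibble::tibble(
    category = eligibility_categories(),
    n = c(608L, 1072L, 11L, 66L, 1150L),
    pct_prescribed = c(70.6, 37.4, 63.6, 16.7, 16.3)
  )
  agreement <- matrix(
    c(413, 52, 25, 15, 14, 56,
       38, 22, 10,  3,  2,  5,
        2,  2,  4,  2,  3,  1,
        1,  1,  0,  4,  4,  0,
        0,  0,  0,  0,  1,  0),
    nrow = 5, byrow = TRUE,
    dimnames = list(documented = risk_levels(), calculated = calculated_levels())
  )
  flow <- tibble::tibble(
    screened = 3087L, excluded_under18 = 158L, excluded_under40_no_risk = 22L,
    included = 2907L, missing_tc = 576L, missing_sbp = 3L, missing_both = 12L,
    documented = 680L
  )
  list(flow = flow, strata = strata, prescribing = prescribing,
       agreement = agreement)
}
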