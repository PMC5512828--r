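#' Index-date measurement selection
#'
#' Each analysis anchors measurement choice to an index date. Prospective
#' selection (used for the enrolment risk profile) takes the earliest
#' non-missing measurement dated on or after the index date. Retrospective
#' selection (used for treatment-eligibility and documented-score accuracy)
#' takes the most recent non-missing measurement dated strictly before the
#' index date: a same-day laboratory value may postdate the clinical
#' decision, so it is excluded by default (`strict = FALSE` relaxes this to
#' on-or-before). When two candidate measurements share the selected date,
#' the first in file order wins and a warning reports the tie count.
#'
#' `first_prospective()` and `first_retrospective()` are single-patient
#' conveniences; `select_measurement()` is the vectorised worker used by
#' the pipeline.
#'
#' @param measurements A measurements table (`patient_id`, `date`, `kind`,
#'   `value`); for the single-patient forms `patient_id` is optional.
#' @param index_date A single index date.
#' @param kind `"sbp"` or `"total_cholesterol"`.
#' @return The selected value, or `NA` if no eligible measurement exists.
#' @export
#' @examples
#' m <- data.frame(date = as.Date("2015-01-01") + c(3, 10),
#'                 kind = "sbp", value = c(150, 140))
#' first_prospective(m, as.Date("2015-01-01"), "sbp")   # 150
#' first_retrospective(m, as.Date("2015-01-11"), "sbp") # 140
first_prospective <- function(measurements, index_date, kind) {
  single_patient_select(measurements, index_date, kind, "prospective")
}

#' @rdname first_prospective
#' @param strict Retrospective only: exclude measurements dated exactly on
#'   the index date (default `TRUE`).
#' @export
first_retrospective <- function(measurements, index_date, kind, strict = TRUE) {
  single_patient_select(measurements, index_date, kind, "retrospective", strict)
}

single_patient_select <- function(measurements, index_date, kind, direction,
                                  strict = TRUE) {
  m <- tibble::as_tibble(measurements)
  if (!"patient_id" %in% names(m)) m$patient_id <- "patient"
  if (length(unique(m$patient_id)) > 1) {
    stop("use select_measurement() for multi-patient tables", call. = FALSE)
  }
  idx <- tibble::tibble(patient_id = m$patient_id[1], index_date = as.Date(index_date))
  if (nrow(m) == 0) return(NA_real_)
  out <- select_measurement(m, idx, kind, direction, strict)
  out$value[1]
}

#' @rdname first_prospective
#' @param index A data frame with columns `patient_id` and `index_date`
#'   (one row per patient to select for).
#' @param direction `"prospective"` or `"retrospective"`.
#' @return `select_measurement()` returns a tibble with one row per `index`
#'   row: `patient_id`, `value` (`NA` when absent), `date` of the selected
#'   measurement, and `n_tied` (number of same-date candidates).
#' @export
select_measurement <- function(measurements, index, kind,
                               direction = c("prospective", "retrospective"),
                               strict = TRUE) {
  direction <- match.arg(direction)
  m <- tibble::as_tibble(measurements)
  m <- m[m$kind == kind & !is.na(m$value), c("patient_id", "date", "value")]
  m$.file_order <- seq_len(nrow(m))
  df <- dplyr::inner_join(tibble::as_tibble(index)[c("patient_id", "index_date")],
                          m, by = "patient_id")
  df <- if (direction == "prospective") {
    df[df$date >= df$index_date, ]
  } else if (strict) {
    df[df$date < df$index_date, ]
  } else {
    df[df$date <= df$index_date, ]
  }
  ord <- if (direction == "prospective") {
    order(df$patient_id, as.numeric(df$date), df$.file_order)
  } else {
    order(df$patient_id, -as.numeric(df$date), df$.file_order)
  }
  df <- df[ord, ]
  sel <- df[!duplicated(df$patient_id), ]
  tie_counts <- dplyr::count(
    dplyr::semi_join(df, sel, by = c("patient_id", "date")), .data$patient_id)
  sel <- dplyr::left_join(sel, tie_counts, by = "patient_id")
  n_tied_total <- sum(sel$n > 1)
  if (n_tied_total > 0) {
    warning(n_tied_total, " patient(s) had same-date ", kind,
            " ties; first record in file order used", call. = FALSE)
  }
  out <- dplyr::left_join(tibble::as_tibble(index)["patient_id"],
                          sel[c("patient_id", "value", "date", "n")],
                          by = "patient_id")
  out$n[is.na(out$n)] <- 0L
  names(out)[names(out) == "n"] <- "n_tied"
  out
}

# ---- imputation ------------------------------------------------------------

#' Impute missing systolic blood pressure with a constant
#'
#' Patients lacking a selected SBP receive a fixed fill value (default 130
#' mmHg, a typical admission mean in adult NCD cohorts where SBP
#' missingness is rare) and are flagged. Observed values are never
#' altered; re-running the imputation is a no-op.
#'
#' @param selected A data frame with a numeric `sbp` column (NA = absent).
#' @param fill Fill value in mmHg (configuration key `sbp_fill_mmHg`).
#' @return The input with `sbp` filled and a logical `sbp_imputed` column.
#' @export
impute_sbp <- function(selected, fill = 130) {
  selected <- tibble::as_tibble(selected)
  already <- if ("sbp_imputed" %in% names(selected)) selected$sbp_imputed else rep(FALSE, nrow(selected))
  filled <- is.na(selected$sbp)
  selected$sbp[filled] <- fill
  selected$sbp_imputed <- already | filled
  selected
}

#' Fit the cholesterol imputation model
#'
#' Ordinary least-squares regression of total cholesterol on three
#' predictors - age (years), sex (indicator, female = 1) and systolic
#' blood pressure (mmHg) - fitted on complete cases. Any full-rank sex
#' coding gives identical predictions; the female indicator is a cosmetic
#' choice.
#'
#' @param complete_cases A data frame with columns `tc`, `age`, `sex`,
#'   `sbp`; rows with any missing field are dropped.
#' @return A `tc_model` object (coefficients, `fit_n`, underlying `lm`).
#' @export
fit_tc_model <- function(complete_cases) {
  d <- tibble::as_tibble(complete_cases)
  d <- d[stats::complete.cases(d[c("tc", "age", "sex", "sbp")]), ]
  d$female <- as.integer(d$sex == "female")
  if (nrow(d) < 4) {
    stop("need at least 4 complete cases to fit the cholesterol model",
         call. = FALSE)
  }
  fit <- stats::lm(tc ~ age + female + sbp, data = d)
  if (anyNA(coef(fit))) {
    stop("rank-deficient design: cholesterol model cannot be fitted",
         call. = FALSE)
  }
  structure(
    list(coefficients = coef(fit), fit_n = nrow(d), fit = fit),
    class = "tc_model"
  )
}

#' @export
print.tc_model <- function(x, ...) {
  cat("<tc_model> OLS imputation model, fitted on", x$fit_n, "complete cases\n")
  print(round(x$coefficients, 4))
  invisible(x)
}

#' @export
predict.tc_model <- function(object, newdata, ...) {
  b <- object$coefficients
  unname(b[1] + b["age"] * newdata$age +
           b["female"] * as.integer(newdata$sex == "female") +
           b["sbp"] * newdata$sbp)
}

#' Impute missing total cholesterol from the regression model
#'
#' Every row lacking a selected TC gets the affine prediction from its age,
#' sex and (already imputed, see [impute_sbp()]) SBP, and is flagged. SBP
#' imputation must precede TC imputation because SBP is a predictor.
#'
#' @param selected A data frame with columns `tc`, `age`, `sex`, `sbp`.
#' @param model A `tc_model` from [fit_tc_model()].
#' @return The input with `tc` filled and a logical `tc_imputed` column.
#' @export
impute_tc <- function(selected, model) {
  stopifnot(inherits(model, "tc_model"))
  selected <- tibble::as_tibble(selected)
  if (anyNA(selected$sbp)) {
    stop("SBP must be imputed before TC (SBP is a model predictor)",
         call. = FALSE)
  }
  already <- if ("tc_imputed" %in% names(selected)) selected$tc_imputed else rep(FALSE, nrow(selected))
  filled <- is.na(selected$tc)
  if (any(filled)) {
    selected$tc[filled] <- predict(model, selected[filled, ])
  }
  selected$tc_imputed <- already | filled
  selected
}
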