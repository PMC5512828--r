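#' Chart axis discretisation
#'
#' The WHO/ISH charts (cholesterol variant) are indexed by six axes: sex,
#' age band, smoking, diabetes, systolic blood pressure band and total
#' cholesterol band. All bands are half-open and lower-inclusive, so a tie
#' value (e.g. SBP 140.0) falls in the higher band. Adults aged 18-39 are
#' scored on the lowest (40-year) chart band: the published charts start at
#' 40, but cohort inclusion admits qualifying adults from 18, and scoring
#' them on the youngest band is the package's documented convention, not a
#' WHO statement.
#'
#' @param age Age in whole years (>= 18).
#' @return `age_band()` returns an integer band label in
#'   `c(40, 50, 60, 70)`; `sbp_band()` and `tc_band()` return character
#'   band labels.
#' @export
#' @examples
#' age_band(c(18, 50, 93))
#' sbp_band(c(139, 160, 210))
#' tc_band(c(4.99, 6.5, 8))
age_band <- function(age) {
  if (any(is.na(age)) || any(age < 18)) {
    stop("age must be >= 18 for chart scoring", call. = FALSE)
  }
  c(40L, 50L, 60L, 70L)[findInterval(age, c(18, 50, 60, 70))]
}

#' @rdname age_band
#' @param sbp Systolic blood pressure in mmHg (> 0).
#' @export
sbp_band <- function(sbp) {
  if (any(is.na(sbp)) || any(sbp <= 0)) stop("sbp must be > 0", call. = FALSE)
  sbp_band_levels()[findInterval(sbp, c(0, 140, 160, 180))]
}

#' @rdname age_band
#' @param tc Total cholesterol in mmol/L (> 0).
#' @export
tc_band <- function(tc) {
  if (any(is.na(tc)) || any(tc <= 0)) stop("tc must be > 0", call. = FALSE)
  tc_band_levels()[findInterval(tc, c(0, 5, 6, 7, 8))]
}

sbp_band_levels <- function() c("<140", "140-159", "160-179", ">=180")
tc_band_levels <- function() c("<5", "5-<6", "6-<7", "7-<8", ">=8")

chart_grid <- function(subregion) {
  g <- expand.grid(
    sex = c("male", "female"), age_band = c(40L, 50L, 60L, 70L),
    smoker = c(FALSE, TRUE), diabetic = c(FALSE, TRUE),
    sbp_band = sbp_band_levels(), tc_band = tc_band_levels(),
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  g$subregion <- subregion
  tibble::as_tibble(g[c("subregion", "sex", "age_band", "smoker", "diabetic",
                        "sbp_band", "tc_band")])
}

chart_key <- function(df) {
  paste(df$sex, df$age_band, df$smoker, df$diabetic, df$sbp_band, df$tc_band,
        sep = "|")
}

#' Synthetic WHO/ISH-style risk chart
#'
#' Builds a complete 640-cell banded risk chart with the qualitative
#' structure of the published WHO/ISH charts: risk increases monotonically
#' with age, SBP, and cholesterol band, and with smoking, diabetes and male
#' sex. Cell categories come from a simple 10-year-hazard model evaluated
#' at band midpoints and cut at 10/20/30/40%. The cell values are
#' synthetic: the licensed chart tables are not redistributed with the
#' package, and every shipped analysis result is independent of specific
#' cell values. A transcription of a real subregion chart in the same CSV
#' layout can be supplied to [load_chart()] instead.
#'
#' @param subregion Chart subregion identifier (default `"EMR-B"`, the
#'   Eastern Mediterranean B subregion covering Jordan and Syria).
#' @return A `whoish_chart` tibble with one row per cell.
#' @export
#' @examples
#' chart <- synthetic_chart()
#' nrow(chart)  # 640
synthetic_chart <- function(subregion = "EMR-B") {
  g <- chart_grid(subregion)
  age_mid <- c(`40` = 45, `50` = 55, `60` = 65, `70` = 75)[as.character(g$age_band)]
  sbp_mid <- c(130, 150, 170, 190)[match(g$sbp_band, sbp_band_levels())]
  tc_mid <- c(4.5, 5.5, 6.5, 7.5, 8.75)[match(g$tc_band, tc_band_levels())]
  lp <- 0.075 * (age_mid - 60) + 0.021 * (sbp_mid - 140) +
    0.28 * (tc_mid - 5.5) + 0.68 * g$smoker + 0.75 * g$diabetic +
    0.40 * (g$sex == "male")
  risk10 <- 1 - exp(-0.03 * exp(lp))
  g$category <- risk_levels()[findInterval(risk10, c(0, 0.10, 0.20, 0.30, 0.40))]
  new_whoish_chart(g)
}

new_whoish_chart <- function(df) {
  structure(tibble::as_tibble(df), class = c("whoish_chart", class(tibble::tibble())))
}

#' Load a risk chart from CSV
#'
#' The chart file has one row per cell and columns `subregion`, `sex`,
#' `age_band`, `smoker`, `diabetic`, `sbp_band`, `tc_band`, `category`.
#' The loader enforces completeness: a chart whose [validate_chart()]
#' report is non-empty is rejected.
#'
#' @param path Path to the chart CSV.
#' @param subregion Optional subregion to select when the file carries
#'   several.
#' @return A `whoish_chart` tibble.
#' @export
load_chart <- function(path, subregion = NULL) {
  chart <- readr::read_csv(path, show_col_types = FALSE,
    col_types = readr::cols(
      subregion = "c", sex = "c", age_band = "i", smoker = "l",
      diabetic = "l", sbp_band = "c", tc_band = "c", category = "c"))
  if (!is.null(subregion)) chart <- chart[chart$subregion == subregion, ]
  chart <- new_whoish_chart(chart)
  report <- validate_chart(chart)
  if (nrow(report) > 0) {
    stop("invalid chart file: ", nrow(report), " issue(s); first: ",
         report$issue[1], " [", report$cell[1], "]", call. = FALSE)
  }
  chart
}

#' Validate a risk chart
#'
#' Reports missing cells, duplicate cells and invalid category labels. An
#' empty report means the chart is complete (all 2 x 4 x 2 x 2 x 4 x 5 =
#' 640 cells per subregion present exactly once with valid categories).
#'
#' @param chart A `whoish_chart` (or compatible data frame).
#' @return A tibble with columns `issue` and `cell`; zero rows when valid.
#' @export
validate_chart <- function(chart) {
  issues <- list()
  bad_cat <- !chart$category %in% risk_levels()
  if (any(bad_cat)) {
    issues[[length(issues) + 1]] <- tibble::tibble(
      issue = "invalid_category",
      cell = paste0(chart_key(chart[bad_cat, ]), " -> ", chart$category[bad_cat]))
  }
  for (sr in unique(chart$subregion)) {
    sub <- chart[chart$subregion == sr, ]
    keys <- chart_key(sub)
    want <- chart_key(chart_grid(sr))
    dup <- unique(keys[duplicated(keys)])
    if (length(dup) > 0) {
      issues[[length(issues) + 1]] <- tibble::tibble(
        issue = "duplicate_cell", cell = paste0(sr, ": ", dup))
    }
    miss <- setdiff(want, keys)
    if (length(miss) > 0) {
      issues[[length(issues) + 1]] <- tibble::tibble(
        issue = "missing_cell", cell = paste0(sr, ": ", miss))
    }
  }
  if (length(issues) == 0) {
    tibble::tibble(issue = character(), cell = character())
  } else {
    dplyr::bind_rows(issues)
  }
}

#' Calculate WHO/ISH risk categories by chart lookup
#'
#' Discretises each input row onto the six chart axes and returns the
#' chart cell category. Scoring depends only on the six axes: any two
#' inputs falling in the same bands receive identical categories.
#'
#' @param input A data frame with columns `sex`, `age`, `smoker`
#'   (logical, per [smoking_positive()]), `diabetic` (logical), `sbp`
#'   (mmHg), `tc` (mmol/L).
#' @param chart A `whoish_chart`, e.g. from [synthetic_chart()] or
#'   [load_chart()].
#' @return An ordered factor over [risk_levels()], one value per row.
#' @export
#' @examples
#' chart <- synthetic_chart()
#' calculate_risk(
#'   data.frame(sex = "male", age = 60, smoker = TRUE, diabetic = TRUE,
#'              sbp = 165, tc = 6.5),
#'   chart
#' )
calculate_risk <- function(input, chart) {
  check_sex(input$sex)
  key <- paste(input$sex, age_band(input$age), as.logical(input$smoker),
               as.logical(input$diabetic), sbp_band(input$sbp),
               tc_band(input$tc), sep = "|")
  idx <- match(key, chart_key(chart))
  if (anyNA(idx)) {
    stop("chart has no cell for: ", key[which(is.na(idx))[1]], call. = FALSE)
  }
  as_risk_category(chart$category[idx])
}
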