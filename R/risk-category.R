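#' WHO/ISH 10-year risk categories
#'
#' The WHO/ISH charts stratify 10-year combined fatal/non-fatal CVD event
#' risk into five ordered bands. `risk_levels()` returns the band labels in
#' increasing order; `calculated_levels()` appends the `history_of_cvd`
#' level used on the calculated side of agreement tables, where patients
#' with established disease are reported as a category of their own rather
#' than a chart score.
#'
#' @return A character vector of category labels.
#' @export
#' @examples
#' risk_levels()
risk_levels <- function() {
  c("<10", "10-<20", "20-<30", "30-<40", ">=40")
}

#' @rdname risk_levels
#' @export
calculated_levels <- function() {
  c(risk_levels(), "history_of_cvd")
}

#' Coerce to an ordered risk category factor
#'
#' @param x A character vector (or factor) of risk band labels.
#' @param extended Include the `history_of_cvd` level (unordered factor used
#'   on the calculated side of agreement tables).
#' @return An ordered factor over [risk_levels()] (or an unordered factor
#'   over [calculated_levels()] when `extended = TRUE`).
#' @export
#' @examples
#' as_risk_category(c("<10", ">=40"))
as_risk_category <- function(x, extended = FALSE) {
  lev <- if (extended) calculated_levels() else risk_levels()
  x <- as.character(x)
  bad <- !is.na(x) & !x %in% lev
  if (any(bad)) {
    stop("invalid risk category label(s): ",
         paste(unique(x[bad]), collapse = ", "), call. = FALSE)
  }
  factor(x, levels = lev, ordered = !extended)
}

#' Binary high/low risk split at the 20% treatment threshold
#'
#' A category counts as high risk when the 10-year risk is at least 20%,
#' the WHO PEN treatment threshold. `history_of_cvd` (secondary prevention)
#' is always high risk.
#'
#' @param x Risk category labels or factor (5- or 6-level).
#' @return Logical vector, `TRUE` for high risk (>= 20% or existing CVD).
#' @export
#' @examples
#' is_high_risk(c("<10", "20-<30", "history_of_cvd"))
is_high_risk <- function(x) {
  x <- as.character(x)
  out <- x %in% c("20-<30", "30-<40", ">=40", "history_of_cvd")
  out[is.na(x)] <- NA
  out
}
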