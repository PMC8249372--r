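#' Construct an indicator series
#'
#' An indicator series holds all observations of one chemical indicator in
#' one water body during one monitoring year. Observations are kept in
#' sampling order; each is either quantified (`censored = FALSE`, `values`
#' holds the measurement) or left-censored (`censored = TRUE`, `values`
#' holds the LOQ). All concentrations are in ug/l. Years are assessed
#' independently: a series never spans years.
#'
#' @param water_body_id Character scalar, e.g. `"PLLW10035"`.
#' @param indicator_id Character scalar, e.g. `"benzo(a)pyrene"`.
#' @param year Integer monitoring year.
#' @param values Numeric vector of concentrations/LOQs, ug/l.
#' @param censored Logical vector parallel to `values`.
#' @param dates Optional vector of sampling dates (character or `Date`),
#'   used to align members of a pesticide sum group.
#'
#' @return An object of class `"indicator_series"`.
#' @export
indicator_series <- function(water_body_id, indicator_id, year,
                             values, censored, dates = NULL) {
  stopifnot(
    is.character(water_body_id), length(water_body_id) == 1L,
    is.character(indicator_id), length(indicator_id) == 1L,
    length(year) == 1L, is.finite(year),
    is.numeric(values), is.logical(censored),
    length(values) == length(censored)
  )
  if (length(values) < 1L) {
    stop("an indicator series needs at least one observation", call. = FALSE)
  }
  if (anyNA(values) || anyNA(censored)) {
    stop("missing values are not allowed in an indicator series",
         call. = FALSE)
  }
  if (any(censored & values <= 0)) {
    stop("censored observations must carry a positive LOQ", call. = FALSE)
  }
  if (any(!censored & values < 0)) {
    stop("quantified concentrations must be non-negative", call. = FALSE)
  }
  if (!is.null(dates) && length(dates) != length(values)) {
    stop("dates must be parallel to the observations", call. = FALSE)
  }
  structure(
    list(water_body_id = water_body_id, indicator_id = indicator_id,
         year = as.integer(year), values = as.numeric(values),
         censored = censored, dates = dates, n = length(values)),
    class = "indicator_series"
  )
}

#' @export
print.indicator_series <- function(x, ...) {
  cat(sprintf("<indicator_series> %s / %s / %d: n = %d (%d censored)\n",
              x$water_body_id, x$indicator_id, x$year, x$n,
              sum(x$censored)))
  cat("  tokens:", paste(format_tokens_short(x), collapse = ", "), "\n")
  invisible(x)
}

format_tokens_short <- function(x) {
  tok <- format(x$values, digits = 4, trim = TRUE)
  tok[x$censored] <- paste0("<", tok[x$censored])
  tok
}
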