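#' Parse a concentration token
#'
#' Monitoring exports report each concentration either as a plain number
#' (a quantified measurement) or as a left-censored token `"<LOQ"` meaning
#' "below the limit of quantification", e.g. `"< 0.001"`. Both `"<x"` and
#' `"< x"` are accepted; the decimal separator is always a point, never a
#' comma.
#'
#' @param token Character scalar, e.g. `"0.003"` or `"< 0.001"`.
#' @param context Optional character scalar naming the source row/column,
#'   prefixed to error messages raised for malformed tokens.
#'
#' @return A list of class `"observation"` with elements `kind`
#'   (`"quantified"` or `"censored"`) and `value` (the measured
#'   concentration, or the LOQ for censored tokens), in ug/l.
#'
#' @examples
#' parse_observation("< 0.001")
#' parse_observation("0.003")
#' @export
parse_observation <- function(token, context = NULL) {
  where <- if (is.null(context)) "" else paste0(context, ": ")
  if (length(token) != 1L || is.na(token)) {
    stop(where, "observation token must be a single non-missing string",
         call. = FALSE)
  }
  tok <- trimws(token)
  if (!nzchar(tok)) stop(where, "empty observation token", call. = FALSE)
  censored <- startsWith(tok, "<")
  num <- if (censored) trimws(substring(tok, 2L)) else tok
  if (grepl(",", num, fixed = TRUE)) {
    stop(where, "comma decimal separator in token '", token,
         "'; use a decimal point", call. = FALSE)
  }
  value <- suppressWarnings(as.numeric(num))
  if (!nzchar(num) || is.na(value)) {
    stop(where, "malformed observation token '", token, "'", call. = FALSE)
  }
  if (censored && value <= 0) {
    stop(where, "censored token '", token,
         "' has a non-positive LOQ", call. = FALSE)
  }
  if (!censored && value < 0) {
    stop(where, "negative concentration '", token, "'", call. = FALSE)
  }
  structure(
    list(kind = if (censored) "censored" else "quantified", value = value),
    class = "observation"
  )
}

#' Format observations back into tokens
#'
#' Inverse of [parse_observation()]: censored values become `"<LOQ"` tokens,
#' quantified values plain numbers. Full precision is kept so that a
#' write/read round trip reproduces every numeric value exactly.
#'
#' @param values Numeric vector of concentrations (LOQs for censored entries).
#' @param censored Logical vector of the same length.
#' @return Character vector of tokens.
#' @export
format_observation <- function(values, censored) {
  stopifnot(length(values) == length(censored))
  tok <- sprintf("%.17g", values)
  tok[censored] <- paste0("<", tok[censored])
  tok
}

# Vectorised token parser used by the readers; returns a data.frame
# (value, censored) and reports the offending row index on failure.
parse_tokens <- function(tokens, rows = seq_along(tokens), column = "value") {
  censored <- logical(length(tokens))
  value <- numeric(length(tokens))
  for (i in seq_along(tokens)) {
    obs <- parse_observation(tokens[[i]],
                             context = sprintf("row %d, column '%s'",
                                               rows[[i]], column))
    censored[i] <- obs$kind == "censored"
    value[i] <- obs$value
  }
  data.frame(value = value, censored = censored)
}
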