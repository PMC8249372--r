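#' Half-LOQ substituted concentrations
#'
#' Applies the substitution rule of Directive 2009/90/EC: every left-censored
#' observation is replaced by half its LOQ; quantified observations pass
#' through unchanged. Order is preserved.
#'
#' @param series An [indicator_series()].
#' @return Numeric vector of concentrations in ug/l.
#' @export
substituted_values <- function(series) {
  stopifnot(inherits(series, "indicator_series"))
  ifelse(series$censored, series$values / 2, series$values)
}

#' Summary statistics of a censored monitoring series
#'
#' Computes the four quantities the status assessment rests on, all from the
#' half-LOQ substituted series:
#'
#' * `mean` — arithmetic mean of the substituted values (the annual average
#'   tested against AA-EQS);
#' * `maximum` — maximum of the substituted values (tested against MAC-EQS);
#' * `stdev_conventional` — ordinary sample standard deviation (divisor
#'   n − 1) of the substituted values;
#' * `stdev_modified` — sample standard deviation in which each censored
#'   observation contributes 0 instead of LOQ/2, while deviations are still
#'   taken from the half-LOQ mean. A series reported entirely below the LOQ
#'   then retains a positive spread, sqrt(n/(n−1))·LOQ/2, instead of the
#'   conventional formula's misleading zero.
#'
#' With no censored observations the two standard deviations coincide. A
#' single observation yields `NA` for both standard deviations.
#'
#' @param series An [indicator_series()].
#' @return A list of class `"series_stats"` with fields `mean`, `maximum`,
#'   `stdev_conventional`, `stdev_modified`, `n`, `n_censored`.
#' @export
series_stats <- function(series) {
  stopifnot(inherits(series, "indicator_series"))
  sub <- substituted_values(series)
  n <- length(sub)
  m <- mean(sub)
  if (n >= 2L) {
    sd_conv <- stats::sd(sub)
    # identical by construction when nothing is censored
    sd_mod <- if (any(series$censored)) {
      zeroed <- ifelse(series$censored, 0, series$values)
      sqrt(sum((zeroed - m)^2) / (n - 1L))
    } else {
      sd_conv
    }
  } else {
    sd_conv <- NA_real_
    sd_mod <- NA_real_
  }
  structure(
    list(mean = m, maximum = max(sub),
         stdev_conventional = sd_conv, stdev_modified = sd_mod,
         n = n, n_censored = sum(series$censored)),
    class = "series_stats"
  )
}

#' @export
print.series_stats <- function(x, ...) {
  cat(sprintf(
    "<series_stats> n = %d (%d censored)\n  mean %.4g  max %.4g  sd(conv) %.4g  sd(mod) %.4g\n",
    x$n, x$n_censored, x$mean, x$maximum,
    x$stdev_conventional, x$stdev_modified))
  invisible(x)
}

# Pick the standard deviation for a named variant.
stdev_for_variant <- function(stats, variant = c("modified", "conventional")) {
  variant <- match.arg(variant)
  if (variant == "modified") stats$stdev_modified else stats$stdev_conventional
}
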