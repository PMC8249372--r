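#' Classify one chemical indicator against its quality standards
#'
#' Good status requires meeting both criteria: the annual mean must not
#' exceed AA-EQS and the maximum must not exceed MAC-EQS. "Exceeds" is
#' strict, so a mean exactly at the threshold is still good. The four
#' classification cases are:
#'
#' * `"i"`   — good: both criteria met;
#' * `"ii"`  — below good: mean exceeds AA-EQS only;
#' * `"iii"` — below good: maximum exceeds MAC-EQS only;
#' * `"iv"`  — below good: both thresholds exceeded.
#'
#' @param stats A [series_stats()] result.
#' @param aa_eqs,mac_eqs Thresholds in ug/l, `mac_eqs >= aa_eqs > 0`.
#' @param indicator_id Indicator label carried into the result.
#' @return A list of class `"indicator_class"` with fields `indicator_id`,
#'   `status` (`"good"`/`"below_good"`), `case`, `mean`, `maximum`,
#'   `aa_eqs`, `mac_eqs`, `stats`.
#' @export
classify_indicator <- function(stats, aa_eqs, mac_eqs,
                               indicator_id = "indicator") {
  stopifnot(inherits(stats, "series_stats"),
            is.finite(aa_eqs), aa_eqs > 0,
            is.finite(mac_eqs), mac_eqs > 0, mac_eqs >= aa_eqs)
  mean_exceeds <- stats$mean > aa_eqs
  max_exceeds <- stats$maximum > mac_eqs
  case <- if (!mean_exceeds && !max_exceeds) "i"
          else if (mean_exceeds && !max_exceeds) "ii"
          else if (!mean_exceeds && max_exceeds) "iii"
          else "iv"
  structure(
    list(indicator_id = indicator_id,
         status = if (case == "i") "good" else "below_good",
         case = case, mean = stats$mean, maximum = stats$maximum,
         aa_eqs = aa_eqs, mac_eqs = mac_eqs, stats = stats),
    class = "indicator_class"
  )
}

#' @export
print.indicator_class <- function(x, ...) {
  cat(sprintf("<indicator_class> %s: %s (case %s)\n  mean %.4g vs AA-EQS %.4g; max %.4g vs MAC-EQS %.4g\n",
              x$indicator_id, x$status, x$case,
              x$mean, x$aa_eqs, x$maximum, x$mac_eqs))
  invisible(x)
}

#' Build the per-date sum series of a pesticide group
#'
#' The aldrin/dieldrin/endrin/isodrin criterion is a threshold on the sum of
#' concentrations. Member series are aligned by sampling date (or by
#' position when no dates are available and all members have the same
#' length), each member's censored observations are substituted at LOQ/2,
#' and the per-date sums form a new, fully quantified series labelled with
#' the group id.
#'
#' @param series_list List of `indicator_series` for the members present in
#'   one (water body, year); at least one.
#' @param group_id Label for the resulting series.
#' @return An [indicator_series()] of per-date sums.
#' @export
sum_group_series <- function(series_list, group_id = "sum_group") {
  stopifnot(length(series_list) >= 1L)
  wb <- unique(vapply(series_list, `[[`, "", "water_body_id"))
  yr <- unique(vapply(series_list, `[[`, 0L, "year"))
  if (length(wb) != 1L || length(yr) != 1L) {
    stop("sum-group members must share one water body and year",
         call. = FALSE)
  }
  subs <- lapply(series_list, substituted_values)
  has_dates <- !vapply(series_list, function(s) is.null(s$dates), TRUE)
  if (all(has_dates)) {
    dates <- lapply(series_list, function(s) as.character(s$dates))
    common <- Reduce(intersect, dates)
    if (length(common) == 0L) {
      stop("sum-group members share no sampling dates", call. = FALSE)
    }
    common <- sort(common)
    total <- Reduce(`+`, Map(function(v, d) v[match(common, d)], subs, dates))
    out_dates <- common
  } else {
    lens <- unique(lengths(subs))
    if (length(lens) != 1L) {
      stop("sum-group members have differing observation counts and no ",
           "dates; alignment impossible", call. = FALSE)
    }
    total <- Reduce(`+`, subs)
    out_dates <- NULL
  }
  indicator_series(wb, group_id, yr, values = total,
                   censored = rep(FALSE, length(total)), dates = out_dates)
}

#' Classify a pesticide sum group
#'
#' Forms the per-date sum series via [sum_group_series()] and classifies it
#' exactly as a single indicator against the group's thresholds.
#'
#' @inheritParams sum_group_series
#' @param aa_eqs,mac_eqs Group thresholds for the sum of concentrations.
#' @return An `"indicator_class"` for the group.
#' @export
classify_sum_group <- function(series_list, aa_eqs, mac_eqs,
                               group_id = "sum_group") {
  s <- sum_group_series(series_list, group_id = group_id)
  classify_indicator(series_stats(s), aa_eqs, mac_eqs,
                     indicator_id = group_id)
}

#' One-out-all-out status of a water body
#'
#' The chemical status is good only if every classified indicator is good; a
#' single below-good indicator downgrades the whole water body. Indicators
#' that were not monitored are simply absent — the status is assessed from
#' the available indicators, never imputed.
#'
#' @param indicator_classes Non-empty list of `"indicator_class"` objects
#'   for one (water body, year).
#' @param water_body_id,year Labels carried into the result.
#' @return A list of class `"water_body_class"` with fields
#'   `water_body_id`, `year`, `status`, `indicator_classes`, `decisive`
#'   (ids of all below-good indicators, sorted).
#' @export
classify_water_body <- function(indicator_classes, water_body_id = "wb",
                                year = NA_integer_) {
  if (length(indicator_classes) == 0L) {
    stop("no classifiable indicators", call. = FALSE)
  }
  stopifnot(all(vapply(indicator_classes, inherits, TRUE,
                       "indicator_class")))
  status <- vapply(indicator_classes, `[[`, "", "status")
  ids <- vapply(indicator_classes, `[[`, "", "indicator_id")
  decisive <- sort(ids[status == "below_good"])
  structure(
    list(water_body_id = water_body_id, year = year,
         status = if (length(decisive) == 0L) "good" else "below_good",
         indicator_classes = indicator_classes, decisive = decisive),
    class = "water_body_class"
  )
}

#' @export
print.water_body_class <- function(x, ...) {
  cat(sprintf("<water_body_class> %s / %s: %s\n", x$water_body_id,
              x$year, x$status))
  if (length(x$decisive) > 0L) {
    cat("  decisive (below good):", paste(x$decisive, collapse = ", "), "\n")
  }
  invisible(x)
}
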