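POM_BIN_LABELS <- c("<0,0.1>", "(0.1,0.3>", "(0.3,0.5>", "(0.5,1>")

#' Bin a misclassification probability
#'
#' Discretises P_om into the four reporting intervals `[0, 0.1]`,
#' `(0.1, 0.3]`, `(0.3, 0.5]`, `(0.5, 1]`. The first interval is closed on
#' both sides so the four bins partition `[0, 1]`.
#'
#' @param p Numeric vector of probabilities in `[0, 1]`.
#' @return Factor with levels `"<0,0.1>"`, `"(0.1,0.3>"`, `"(0.3,0.5>"`,
#'   `"(0.5,1>"`.
#' @export
bin_pom <- function(p) {
  if (any(!is.finite(p)) || any(p < -1e-12) || any(p > 1 + 1e-12)) {
    stop("P_om values must lie in [0, 1]", call. = FALSE)
  }
  cut(pmin(pmax(p, 0), 1), breaks = c(-Inf, 0.1, 0.3, 0.5, Inf),
      labels = POM_BIN_LABELS, right = TRUE)
}

#' Status-level (Level 4) misclassification probability
#'
#' Aggregates the per-indicator Level-3 probabilities of one water body to
#' the single status P_om. For a good-status water body the maximum over
#' all indicators is taken; for a below-good water body only the decisive
#' (below-good) indicators count — good indicators are not decisive for the
#' status and are ignored. Ties are broken toward the lexicographically
#' smallest indicator id so reports are deterministic.
#'
#' @param wb A [classify_water_body()] result.
#' @param level3 Named numeric vector of Level-3 P_om values covering every
#'   classified indicator of `wb`.
#' @return A list of class `"water_body_pom"` with fields `water_body_id`,
#'   `year`, `status`, `level3`, `level4`, `decisive_indicator`, `bin`.
#' @export
status_pom <- function(wb, level3) {
  stopifnot(inherits(wb, "water_body_class"), is.numeric(level3))
  ids <- vapply(wb$indicator_classes, `[[`, "", "indicator_id")
  missing_ids <- setdiff(ids, names(level3))
  if (length(missing_ids) > 0L) {
    stop("level3 lacks indicator(s): ",
         paste(missing_ids, collapse = ", "), call. = FALSE)
  }
  relevant <- if (wb$status == "good") ids else wb$decisive
  if (length(relevant) == 0L) {
    stop("no relevant indicators for the status P_om", call. = FALSE)
  }
  vals <- level3[relevant]
  level4 <- max(vals)
  decisive <- min(names(vals)[vals == level4])
  structure(
    list(water_body_id = wb$water_body_id, year = wb$year,
         status = wb$status, level3 = level3, level4 = level4,
         decisive_indicator = decisive,
         bin = as.character(bin_pom(level4))),
    class = "water_body_pom"
  )
}

#' @export
print.water_body_pom <- function(x, ...) {
  cat(sprintf("<water_body_pom> %s / %s: %s, P_om = %.3g (%s), decisive %s\n",
              x$water_body_id, x$year, x$status, x$level4, x$bin,
              x$decisive_indicator))
  invisible(x)
}

#' Assess chemical status and its misclassification probability
#'
#' Runs the whole procedure: summary statistics under half-LOQ substitution,
#' per-indicator classification against the EQS table (with the pesticide
#' sum rule), criterion-level P_om by Student t (mean) and Gumbel (maximum),
#' Level-3 composition, one-out-all-out status, and the Level-4 status P_om
#' with its interval bin. Both standard-deviation variants can be carried
#' through in one run for side-by-side comparison.
#'
#' Indicators without an EQS entry are skipped. Series with a single
#' observation are classified but carry `NA` probabilities and are excluded
#' from the Level-3/Level-4 aggregation.
#'
#' @param measurements A path to a measurements file, a long-format data
#'   frame, or a list of [indicator_series()].
#' @param eqs A path to an EQS file or an `"eqs_table"` data frame.
#' @param stdev_variant `"modified"`, `"conventional"` or `"both"`.
#' @param fit_method Gumbel fit for the maximum criterion, `"moments"`
#'   (default) or `"mle"`.
#' @param truncate Renormalise the mean-criterion t distribution over the
#'   non-negative half line; default `FALSE`.
#' @return A list of class `"pom_assessment"` with two data frames:
#'   `indicators` (one row per water body, year, indicator and variant:
#'   statistics, class, case, criterion P_oms, Level-3 P_om) and `status`
#'   (one row per water body, year and variant: status, decisive indicator,
#'   its criterion P_oms, Level-4 P_om, bin).
#' @export
assess <- function(measurements, eqs,
                   stdev_variant = c("modified", "conventional", "both"),
                   fit_method = c("moments", "mle"),
                   truncate = FALSE) {
  stdev_variant <- match.arg(stdev_variant)
  fit_method <- match.arg(fit_method)
  variants <- if (stdev_variant == "both") {
    c("conventional", "modified")
  } else {
    stdev_variant
  }
  series_list <- resolve_measurements(measurements)
  eqs <- resolve_eqs(eqs)

  wb_year <- unique(data.frame(
    wb = vapply(series_list, `[[`, "", "water_body_id"),
    year = vapply(series_list, `[[`, 0L, "year")
  ))
  ind_rows <- list()
  st_rows <- list()
  for (k in seq_len(nrow(wb_year))) {
    wb_id <- wb_year$wb[k]
    yr <- wb_year$year[k]
    group <- Filter(function(s) {
      s$water_body_id == wb_id && s$year == yr
    }, series_list)
    assembled <- assemble_assessable(group, eqs)
    if (length(assembled) == 0L) next
    classes <- lapply(assembled, function(a) {
      classify_indicator(series_stats(a$series), a$aa_eqs, a$mac_eqs,
                         indicator_id = a$indicator_id)
    })
    wb_class <- classify_water_body(classes, water_body_id = wb_id,
                                    year = yr)
    for (variant in variants) {
      level3 <- numeric(0)
      for (j in seq_along(classes)) {
        cls <- classes[[j]]
        st <- cls$stats
        row <- data.frame(
          wb_id = wb_id, year = yr, indicator = cls$indicator_id,
          stdev_variant = variant, n = st$n, n_censored = st$n_censored,
          mean = st$mean, maximum = st$maximum,
          stdev = stdev_for_variant(st, variant),
          status = cls$status, case = cls$case,
          pom_mean = NA_real_, pom_max = NA_real_, level3 = NA_real_,
          stringsAsFactors = FALSE
        )
        if (st$n >= 2L) {
          pm <- pom_mean(st$mean, stdev_for_variant(st, variant), st$n,
                         cls$aa_eqs,
                         assessed = if (st$mean > cls$aa_eqs)
                           "below_good" else "good",
                         truncate = truncate, stdev_variant = variant)
          px <- pom_max(substituted_values(assembled[[j]]$series), st,
                        cls$mac_eqs,
                        assessed = if (st$maximum > cls$mac_eqs)
                          "below_good" else "good",
                        fit_method = fit_method, stdev_variant = variant)
          row$pom_mean <- pm$p_om
          row$pom_max <- px$p_om
          row$level3 <- indicator_pom(cls, pm, px)
          level3[cls$indicator_id] <- row$level3
        }
        ind_rows[[length(ind_rows) + 1L]] <- row
      }
      usable_ids <- names(level3)
      relevant <- if (wb_class$status == "good") usable_ids else
        intersect(wb_class$decisive, usable_ids)
      if (length(relevant) == 0L) next
      sub_wb <- wb_class
      sub_wb$indicator_classes <- Filter(function(c) {
        c$indicator_id %in% usable_ids
      }, wb_class$indicator_classes)
      sub_wb$decisive <- intersect(wb_class$decisive, usable_ids)
      wbp <- status_pom(sub_wb, level3)
      dec_row <- vapply(ind_rows, function(r) {
        r$wb_id == wb_id && r$year == yr &&
          r$indicator == wbp$decisive_indicator &&
          r$stdev_variant == variant
      }, TRUE)
      dec <- ind_rows[[which(dec_row)[1L]]]
      st_rows[[length(st_rows) + 1L]] <- data.frame(
        wb_id = wb_id, year = yr, stdev_variant = variant,
        status = wb_class$status,
        n_indicators = length(classes),
        decisive_indicator = wbp$decisive_indicator,
        pom_mean = dec$pom_mean, pom_max = dec$pom_max,
        level4 = wbp$level4, bin = wbp$bin,
        stringsAsFactors = FALSE
      )
    }
  }
  structure(
    list(indicators = bind_rows_base(ind_rows),
         status = bind_rows_base(st_rows),
         stdev_variant = stdev_variant, fit_method = fit_method,
         truncate = truncate),
    class = "pom_assessment"
  )
}

#' @export
print.pom_assessment <- function(x, ...) {
  cat(sprintf("<pom_assessment> %d water-body/year assessments, %d indicator rows\n",
              nrow(unique(x$status[c("wb_id", "year")])),
              nrow(x$indicators)))
  cat(sprintf("  stdev variant: %s; Gumbel fit: %s; truncated support: %s\n",
              x$stdev_variant, x$fit_method, x$truncate))
  if (nrow(x$status) > 0L) {
    tab <- table(x$status$stdev_variant, x$status$status)
    print(tab)
  }
  invisible(x)
}

#' Tabulate status P_om values by interval
#'
#' Counts and percentages of assessments per P_om interval, within groups
#' (by default the standard-deviation variant and the assessed status, the
#' layout used for national summaries). Percentages sum to 100 within each
#' group.
#'
#' @param status Data frame with at least `level4` — typically the `status`
#'   element of an [assess()] result — or a `"pom_assessment"`.
#' @param by Character vector of grouping columns present in `status`.
#' @return A data frame of class `"bin_summary"` with one row per group and
#'   bin: `n`, `pct`.
#' @export
summarize_bins <- function(status, by = c("stdev_variant", "status")) {
  if (inherits(status, "pom_assessment")) status <- status$status
  stopifnot(is.data.frame(status), nrow(status) > 0L,
            "level4" %in% names(status))
  by <- intersect(by, names(status))
  bins <- bin_pom(status$level4)
  key <- if (length(by) == 0L) rep("all", nrow(status)) else
    interaction(status[by], drop = TRUE, lex.order = TRUE)
  out <- list()
  for (g in levels(factor(key))) {
    idx <- key == g
    counts <- table(bins[idx])
    grp <- if (length(by) == 0L) data.frame(row.names = 1L) else
      utils::head(status[idx, by, drop = FALSE], 1L)
    rows <- data.frame(
      grp, bin = factor(POM_BIN_LABELS, levels = POM_BIN_LABELS),
      n = as.integer(counts[POM_BIN_LABELS]),
      pct = 100 * as.integer(counts[POM_BIN_LABELS]) / sum(counts),
      row.names = NULL, stringsAsFactors = FALSE
    )
    out[[g]] <- rows
  }
  res <- bind_rows_base(out)
  class(res) <- c("bin_summary", "data.frame")
  res
}

#' Stacked-bar plot of a bin summary
#'
#' Renders the percentage of assessments per P_om interval as stacked bars,
#' one bar per group. Requires ggplot2.
#'
#' @param summary A [summarize_bins()] result.
#' @param x Column of `summary` to place on the x axis.
#' @return A ggplot object.
#' @export
plot_bin_summary <- function(summary, x = "stdev_variant") {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting", call. = FALSE)
  }
  stopifnot(inherits(summary, "bin_summary"), x %in% names(summary))
  ggplot2::ggplot(summary,
                  ggplot2::aes(x = .data[[x]], y = .data[["pct"]],
                               fill = .data[["bin"]])) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::scale_fill_brewer(palette = "RdYlGn", direction = -1,
                               name = "P_om interval") +
    ggplot2::labs(y = "% of assessments", x = NULL) +
    ggplot2::theme_minimal()
}

# --- internal helpers -------------------------------------------------------

resolve_measurements <- function(measurements) {
  if (is.character(measurements) && length(measurements) == 1L) {
    read_measurements(measurements)
  } else if (is.data.frame(measurements)) {
    measurements_from_df(measurements)
  } else if (is.list(measurements)) {
    stopifnot(all(vapply(measurements, inherits, TRUE, "indicator_series")))
    measurements
  } else {
    stop("unrecognised measurements input", call. = FALSE)
  }
}

resolve_eqs <- function(eqs) {
  if (is.character(eqs) && length(eqs) == 1L) {
    read_eqs(eqs)
  } else if (inherits(eqs, "eqs_table")) {
    eqs
  } else if (is.data.frame(eqs)) {
    eqs_from_df(eqs)
  } else {
    stop("unrecognised EQS input", call. = FALSE)
  }
}

# For one (wb, year): pair each series with its thresholds; sum-group
# members are pooled into the group's summed series and never assessed
# individually.
assemble_assessable <- function(group, eqs) {
  out <- list()
  ids <- vapply(group, `[[`, "", "indicator_id")
  member_of <- eqs$member_of[match(ids, eqs$indicator)]
  plain <- which(is.na(member_of))
  for (i in plain) {
    row <- match(ids[i], eqs$indicator)
    if (is.na(row) || eqs$is_sum_group[row]) next
    out[[length(out) + 1L]] <- list(
      series = group[[i]], indicator_id = ids[i],
      aa_eqs = eqs$aa_eqs[row], mac_eqs = eqs$mac_eqs[row]
    )
  }
  for (lab in unique(member_of[!is.na(member_of)])) {
    members <- group[which(member_of == lab)]
    row <- match(lab, eqs$indicator)
    if (is.na(row)) {
      stop("sum group '", lab, "' has no threshold row", call. = FALSE)
    }
    summed <- sum_group_series(members, group_id = lab)
    out[[length(out) + 1L]] <- list(
      series = summed, indicator_id = lab,
      aa_eqs = eqs$aa_eqs[row], mac_eqs = eqs$mac_eqs[row]
    )
  }
  out
}

bind_rows_base <- function(rows) {
  if (length(rows) == 0L) return(data.frame())
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
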