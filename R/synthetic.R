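#' Configuration for the synthetic monitoring generator
#'
#' Describes a stated world of water bodies monitored for a set of chemical
#' indicators. Each indicator has a lognormal true concentration
#' distribution (the standard positive-support model for micro-pollutant
#' series, which typically show considerable variance), an LOQ below which
#' draws are reported as censored tokens, and its EQS thresholds. Defaults:
#' 12 observations per year (the monthly minimum monitoring frequency) and
#' a log-scale standard deviation of 0.5 (coefficient of variation about
#' 53%).
#'
#' @param indicators Data frame with columns `indicator`, `meanlog`,
#'   `sdlog`, `loq`, `aa_eqs`, `mac_eqs`. `sdlog = 0` gives a degenerate
#'   constant concentration (useful for edge-case tests).
#' @param n_water_bodies Number of water bodies.
#' @param n_per_year Observations per indicator and year.
#' @param years Integer vector of monitoring years.
#' @param seed Integer; fixes the generated tables byte-for-byte.
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(indicators, n_water_bodies = 10L, n_per_year = 12L,
                       years = 2016:2018, seed = 1L) {
  needed <- c("indicator", "meanlog", "sdlog", "loq", "aa_eqs", "mac_eqs")
  stopifnot(is.data.frame(indicators), all(needed %in% names(indicators)),
            n_water_bodies >= 1L, n_per_year >= 1L, length(years) >= 1L)
  if (any(indicators$loq <= 0) || any(indicators$sdlog < 0)) {
    stop("loq must be positive and sdlog non-negative", call. = FALSE)
  }
  structure(
    list(indicators = indicators,
         n_water_bodies = as.integer(n_water_bodies),
         n_per_year = as.integer(n_per_year),
         years = as.integer(years), seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Indicator table mirroring three typical priority substances
#'
#' A ready-made indicator set for examples and tests: benzo(a)pyrene,
#' fluoranthene and endosulfan with their AA-EQS/MAC-EQS thresholds and
#' realistic LOQs. True means default to `mean_ratio` times AA-EQS (waters
#' near the classification threshold, the regime where misclassification
#' matters), with `sdlog = 0.5`.
#'
#' @param mean_ratio True mean as a multiple of AA-EQS.
#' @param sdlog Log-scale standard deviation of the lognormal truth.
#' @return Data frame suitable for [sim_config()].
#' @export
example_indicators <- function(mean_ratio = 0.8, sdlog = 0.5) {
  aa <- c(1.7e-4, 0.006, 0.005)
  mac <- c(0.27, 0.12, 0.01)
  loq <- c(5e-5, 1e-3, 1e-3)
  true_mean <- mean_ratio * aa
  data.frame(
    indicator = c("benzo(a)pyrene", "fluoranthene", "endosulfan"),
    meanlog = log(true_mean) - sdlog^2 / 2,
    sdlog = sdlog, loq = loq, aa_eqs = aa, mac_eqs = mac,
    stringsAsFactors = FALSE
  )
}

#' Generate synthetic monitoring tables
#'
#' Draws, for every (water body, indicator, year), `n_per_year` independent
#' concentrations from the indicator's lognormal distribution; draws below
#' the LOQ are emitted as censored tokens `"<loq"`. Alongside the
#' measurements the generator writes the EQS table and a truth table with
#' the true annual-mean concentration and the true class, so downstream
#' calibration never has to re-derive the truth.
#'
#' The true class is good unless the true mean exceeds AA-EQS or the median
#' annual maximum (the `0.5^(1/n)` quantile of the concentration
#' distribution) exceeds MAC-EQS.
#'
#' @param config A [sim_config()].
#' @return A list of class `"synthetic_monitoring"` with data frames
#'   `measurements` (`wb_id`, `indicator`, `year`, `date`, `value` token),
#'   `eqs` and `truth` (`wb_id`, `indicator`, `year`, `true_mean`,
#'   `true_exceeds_aa`, `true_exceeds_mac`, `true_class`,
#'   `censoring_fraction` expected under the LOQ).
#' @export
generate_monitoring <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) {
    assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(config$seed)
  ind <- config$indicators
  wbs <- sprintf("SYNTH%04d", seq_len(config$n_water_bodies))
  # Monthly sampling dates for the regulatory n = 12; unique ISO-8601
  # timestamps spread over the year for denser experimental designs.
  dates <- function(year, n) {
    if (n <= 12L) {
      sprintf("%d-%02d-15", year, seq_len(n))
    } else {
      t0 <- as.POSIXct(sprintf("%d-01-01", year), tz = "UTC")
      format(t0 + round(seq(0, 365 * 86400 - 1, length.out = n)),
             "%Y-%m-%dT%H:%M:%S")
    }
  }
  meas <- list()
  truth <- list()
  for (wb in wbs) {
    for (i in seq_len(nrow(ind))) {
      for (yr in config$years) {
        n <- config$n_per_year
        x <- if (ind$sdlog[i] == 0) {
          rep(exp(ind$meanlog[i]), n)
        } else {
          stats::rlnorm(n, ind$meanlog[i], ind$sdlog[i])
        }
        cens <- x < ind$loq[i]
        token <- sprintf("%.17g", x)
        token[cens] <- sprintf("<%.17g", ind$loq[i])
        meas[[length(meas) + 1L]] <- data.frame(
          wb_id = wb, indicator = ind$indicator[i], year = yr,
          date = dates(yr, n), value = token, stringsAsFactors = FALSE
        )
        true_mean <- exp(ind$meanlog[i] + ind$sdlog[i]^2 / 2)
        med_max <- if (ind$sdlog[i] == 0) exp(ind$meanlog[i]) else
          stats::qlnorm(0.5^(1 / n), ind$meanlog[i], ind$sdlog[i],
                        lower.tail = FALSE)
        exceeds_aa <- true_mean > ind$aa_eqs[i]
        exceeds_mac <- med_max > ind$mac_eqs[i]
        cens_frac <- if (ind$sdlog[i] == 0) {
          as.numeric(exp(ind$meanlog[i]) < ind$loq[i])
        } else {
          stats::plnorm(ind$loq[i], ind$meanlog[i], ind$sdlog[i])
        }
        truth[[length(truth) + 1L]] <- data.frame(
          wb_id = wb, indicator = ind$indicator[i], year = yr,
          true_mean = true_mean, true_exceeds_aa = exceeds_aa,
          true_exceeds_mac = exceeds_mac,
          true_class = if (exceeds_aa || exceeds_mac) "below_good" else
            "good",
          censoring_fraction = cens_frac, stringsAsFactors = FALSE
        )
      }
    }
  }
  structure(
    list(
      measurements = bind_rows_base(meas),
      eqs = eqs_from_df(data.frame(
        indicator = ind$indicator, aa_eqs = ind$aa_eqs,
        mac_eqs = ind$mac_eqs, stringsAsFactors = FALSE
      )),
      truth = bind_rows_base(truth),
      config = config
    ),
    class = "synthetic_monitoring"
  )
}

#' Write a synthetic data set to disk
#'
#' @param sim A [generate_monitoring()] result.
#' @param dir Output directory; created if absent.
#' @return `dir`, invisibly. Writes `measurements.csv`, `eqs.csv`,
#'   `truth.csv`.
#' @export
write_synthetic <- function(sim, dir) {
  stopifnot(inherits(sim, "synthetic_monitoring"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(sim$measurements, file.path(dir, "measurements.csv"),
                   row.names = FALSE, quote = FALSE)
  eqs <- sim$eqs
  eqs$members <- NULL
  eqs$member_of <- NULL
  utils::write.csv(eqs, file.path(dir, "eqs.csv"), row.names = FALSE,
                   quote = FALSE)
  utils::write.csv(sim$truth, file.path(dir, "truth.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' Calibration experiment against known truth
#'
#' Generates a synthetic cohort, runs the full assessment, joins the truth
#' table at indicator level and reports how often the assessed class
#' disagrees with the true class, overall and within each P_om interval. A
#' well-calibrated P_om should show empirical error frequencies increasing
#' across the bins and roughly matching the mean P_om within each bin.
#'
#' @param config A [sim_config()].
#' @param stdev_variant Which standard deviation feeds the probabilities.
#' @param fit_method Gumbel fit for the maximum criterion.
#' @return A list of class `"recovery_report"`: `overall` (data frame with
#'   the cohort-wide error frequency) and `by_bin` (per P_om interval:
#'   number of indicator assessments, mean P_om, empirical error
#'   frequency), plus the joined `detail` table.
#' @export
recovery_experiment <- function(config,
                                stdev_variant = c("modified",
                                                  "conventional"),
                                fit_method = c("moments", "mle")) {
  stdev_variant <- match.arg(stdev_variant)
  fit_method <- match.arg(fit_method)
  sim <- generate_monitoring(config)
  res <- assess(sim$measurements, sim$eqs, stdev_variant = stdev_variant,
                fit_method = fit_method)
  ind <- res$indicators
  key <- function(d) paste(d$wb_id, d$indicator, d$year, sep = "\r")
  truth <- sim$truth
  ind$true_class <- truth$true_class[match(key(ind), key(truth))]
  ind$error <- ind$status != ind$true_class
  ind <- ind[!is.na(ind$level3), , drop = FALSE]
  ind$bin <- bin_pom(ind$level3)
  by_bin <- do.call(rbind, lapply(POM_BIN_LABELS, function(b) {
    sub <- ind[ind$bin == b, , drop = FALSE]
    data.frame(bin = b, n = nrow(sub),
               mean_pom = if (nrow(sub)) mean(sub$level3) else NA_real_,
               error_freq = if (nrow(sub)) mean(sub$error) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  overall <- data.frame(n = nrow(ind), error_freq = mean(ind$error),
                        mean_pom = mean(ind$level3))
  structure(list(overall = overall, by_bin = by_bin, detail = ind),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("<recovery_report> %d indicator assessments, error frequency %.3f (mean P_om %.3f)\n",
              x$overall$n, x$overall$error_freq, x$overall$mean_pom))
  print(x$by_bin, row.names = FALSE)
  invisible(x)
}
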