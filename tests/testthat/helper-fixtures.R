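# The three printed six-observation series from lacustrine water bodies:
# benzo(a)pyrene (two quantified values), fluoranthene (three quantified),
# endosulfan (entirely below the LOQ). Concentrations in ug/l.

table2_series <- function(which = c("bap", "fluo", "endo")) {
  which <- match.arg(which)
  switch(which,
    bap = indicator_series(
      "PLLW10035", "benzo(a)pyrene", 2017L,
      values = c(5e-5, 8e-4, 8e-5, 5e-5, 5e-5, 5e-5),
      censored = c(TRUE, FALSE, FALSE, TRUE, TRUE, TRUE)
    ),
    fluo = indicator_series(
      "PLLW10051", "fluoranthene", 2017L,
      values = c(9e-3, 3e-3, 1e-3, 1e-3, 7e-3, 1e-3),
      censored = c(FALSE, FALSE, TRUE, TRUE, FALSE, TRUE)
    ),
    endo = indicator_series(
      "PLLW10015", "endosulfan", 2017L,
      values = rep(1e-3, 6), censored = rep(TRUE, 6)
    )
  )
}

table2_eqs <- function(which = c("bap", "fluo", "endo")) {
  which <- match.arg(which)
  switch(which,
    bap = list(aa = 1.7e-4, mac = 0.27),
    fluo = list(aa = 0.006, mac = 0.12),
    endo = list(aa = 0.005, mac = 0.01)
  )
}

table2_measurements_df <- function() {
  data.frame(
    wb_id = rep(c("PLLW10035", "PLLW10051", "PLLW10015"), each = 6),
    indicator = rep(c("benzo(a)pyrene", "fluoranthene", "endosulfan"),
                    each = 6),
    year = 2017L,
    value = c("<0.00005", "0.0008", "0.00008", "<0.00005", "<0.00005",
              "<0.00005",
              "0.009", "0.003", "<0.001", "<0.001", "0.007", "<0.001",
              rep("< 0.001", 6)),
    stringsAsFactors = FALSE
  )
}

table2_eqs_df <- function() {
  data.frame(
    indicator = c("benzo(a)pyrene", "fluoranthene", "endosulfan"),
    aa_eqs = c(1.7e-4, 0.006, 0.005),
    mac_eqs = c(0.27, 0.12, 0.01),
    stringsAsFactors = FALSE
  )
}

# Random small series with mixed censoring for property tests.
random_series <- function(n = NULL, common_loq = FALSE,
                          indicator_id = NULL) {
  if (is.null(n)) n <- sample(2:12, 1L)
  if (is.null(indicator_id)) {
    indicator_id <- sprintf("x%06d", sample.int(999999L, 1L))
  }
  loq <- if (common_loq) rep(10^runif(1, -4, -1), n) else
    10^runif(n, -4, -1)
  censored <- runif(n) < 0.4
  values <- ifelse(censored, loq, 10^runif(n, -4, 0))
  indicator_series("WB", indicator_id, 2017L, values = values,
                   censored = censored)
}

# A minimal good-class indicator_class, for composing level-3 values.
good_class_fixture <- function(id = "x") {
  s <- indicator_series("WB", id, 2017L, values = c(0.1, 0.2),
                        censored = c(FALSE, FALSE))
  classify_indicator(series_stats(s), aa_eqs = 1, mac_eqs = 2,
                     indicator_id = id)
}
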