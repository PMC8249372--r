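stats_fixture <- function(mean, maximum) {
  # indicator_class only consults mean and maximum of the stats
  structure(list(mean = mean, maximum = maximum,
                 stdev_conventional = 0.1, stdev_modified = 0.1,
                 n = 6L, n_censored = 0L), class = "series_stats")
}

test_that("indicators land in the four classification cases", {
  # Table 2(a): neither threshold exceeded -> good, case i
  cls <- classify_indicator(series_stats(table2_series("bap")),
                            aa_eqs = 1.7e-4, mac_eqs = 0.27,
                            indicator_id = "benzo(a)pyrene")
  expect_identical(cls$status, "good")
  expect_identical(cls$case, "i")
  # mean criterion exceeded only -> case ii
  cls <- classify_indicator(stats_fixture(0.008, 0.05), 0.006, 0.12)
  expect_identical(cls$status, "below_good")
  expect_identical(cls$case, "ii")
  # maximum criterion exceeded only -> case iii
  cls <- classify_indicator(stats_fixture(0.004, 0.2), 0.006, 0.12)
  expect_identical(cls$case, "iii")
  # both exceeded -> case iv
  cls <- classify_indicator(stats_fixture(0.008, 0.2), 0.006, 0.12)
  expect_identical(cls$case, "iv")
})

test_that("thresholds are sharp: equality is good, any excess flips", {
  at <- classify_indicator(stats_fixture(0.006, 0.12), 0.006, 0.12)
  expect_identical(at$status, "good")
  for (eps in c(1e-12, 1e-9, 1e-3)) {
    above <- classify_indicator(stats_fixture(0.006 * (1 + eps), 0.1),
                                0.006, 0.12)
    expect_identical(above$case, "ii")
  }
})

test_that("every random stats/threshold combination lands in exactly one case", {
  withr::local_seed(5)
  for (rep in 1:200) {
    m <- runif(1, 0, 2)
    mx <- m + runif(1, 0, 2)
    aa <- runif(1, 0.1, 1.5)
    mac <- aa + runif(1, 0, 2)
    cls <- classify_indicator(stats_fixture(m, mx), aa, mac)
    expect_true(cls$case %in% c("i", "ii", "iii", "iv"))
    expect_identical(cls$status == "good", cls$case == "i")
    expect_identical(cls$case %in% c("ii", "iv"), m > aa)
    expect_identical(cls$case %in% c("iii", "iv"), mx > mac)
  }
})

test_that("sum groups are summed per date after substitution", {
  mk <- function(ind, values, censored, dates = NULL) {
    indicator_series("WB", ind, 2017L, values = values,
                     censored = censored, dates = dates)
  }
  dts <- sprintf("2017-%02d-15", 1:6)
  # two members, each entirely censored at LOQ 0.001
  a <- mk("aldrin", rep(1e-3, 6), rep(TRUE, 6), dts)
  d <- mk("dieldrin", rep(1e-3, 6), rep(TRUE, 6), dts)
  s <- sum_group_series(list(a, d), group_id = "pesticides")
  expect_equal(s$values, rep(0.001, 6))
  expect_false(any(s$censored))
  # brute-force per-date oracle on quantified members
  b <- mk("aldrin", c(0.002, 0.004), c(FALSE, FALSE), c("d1", "d2"))
  e <- mk("dieldrin", c(0.003, 0.001), c(FALSE, FALSE), c("d2", "d1"))
  s <- sum_group_series(list(b, e), group_id = "pesticides")
  expect_equal(s$values[match(c("d1", "d2"), s$dates)],
               c(0.002 + 0.001, 0.004 + 0.003))
  # a single present member reduces to its substituted series
  s <- sum_group_series(list(a), group_id = "pesticides")
  expect_equal(s$values, substituted_values(a))
  # no dates and unequal lengths -> alignment impossible
  f <- mk("aldrin", c(0.1, 0.2), c(FALSE, FALSE))
  g <- mk("dieldrin", c(0.1, 0.2, 0.3), rep(FALSE, 3))
  expect_error(sum_group_series(list(f, g)), "alignment impossible")
  # classification of the summed series against group thresholds
  cls <- classify_sum_group(list(a, d), aa_eqs = 0.0005, mac_eqs = 0.01,
                            group_id = "pesticides")
  expect_identical(cls$case, "ii")
  expect_equal(cls$mean, 0.001)
})

test_that("one-out-all-out downgrades on any below-good indicator", {
  good <- function(id) classify_indicator(stats_fixture(0.1, 0.2), 1, 2,
                                          indicator_id = id)
  bad <- function(id) classify_indicator(stats_fixture(1.5, 0.2), 1, 2,
                                         indicator_id = id)
  wb <- classify_water_body(list(good("a"), good("b"), good("c")))
  expect_identical(wb$status, "good")
  expect_length(wb$decisive, 0L)

  wb <- classify_water_body(list(good("a"), bad("b")))
  expect_identical(wb$status, "below_good")
  expect_identical(wb$decisive, "b")

  many <- c(lapply(sprintf("i%02d", 1:44), good), list(bad("z")))
  expect_identical(classify_water_body(many)$status, "below_good")

  expect_error(classify_water_body(list()), "no classifiable")
})

test_that("adding an indicator never improves water-body status", {
  withr::local_seed(17)
  good <- classify_indicator(stats_fixture(0.1, 0.2), 1, 2, "g")
  for (rep in 1:30) {
    n <- sample(1:6, 1)
    classes <- lapply(seq_len(n), function(i) {
      classify_indicator(stats_fixture(runif(1, 0, 2), runif(1, 0, 3)),
                         1, 2, indicator_id = paste0("i", i))
    })
    before <- classify_water_body(classes)$status
    extra <- classify_indicator(stats_fixture(runif(1, 0, 2),
                                              runif(1, 0, 3)), 1, 2, "x")
    after <- classify_water_body(c(classes, list(extra)))$status
    if (before == "below_good") expect_identical(after, "below_good")
    if (after == "good") expect_identical(before, "good")
  }
})
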