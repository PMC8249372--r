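# Independent quadrature oracle for the mean criterion: integrate the t
# density (location mean, scale stdev/sqrt(n), df n-1) over [0 or -Inf, aa].
quad_pom_mean <- function(mean, stdev, n, aa, truncate = FALSE) {
  scale <- stdev / sqrt(n)
  dens <- function(x) dt((x - mean) / scale, df = n - 1) / scale
  lower <- if (truncate) 0 else -Inf
  num <- integrate(dens, lower, aa, rel.tol = 1e-12)$value
  if (truncate) {
    z <- integrate(dens, 0, Inf, rel.tol = 1e-12)$value
    num <- num / z
  }
  1 - num
}

# Quadrature oracle for the maximum criterion under the moments Gumbel fit.
quad_pom_max <- function(mean, stdev, mac) {
  beta <- stdev * sqrt(6) / pi
  mu <- mean - 0.57721566490153286 * beta
  dens <- function(x) {
    z <- (x - mu) / beta
    exp(-z - exp(-z)) / beta
  }
  1 - integrate(dens, -Inf, mac, rel.tol = 1e-12)$value
}

test_that("zero spread collapses the mean criterion to certainty", {
  st <- series_stats(table2_series("endo"))
  p <- pom_mean(st$mean, st$stdev_conventional, st$n, aa_eqs = 0.005,
                assessed = "good", stdev_variant = "conventional")
  expect_identical(p$p_om, 0)
  expect_identical(p$p_class, 1)
})

test_that("a mean sitting on the threshold is a coin flip", {
  p <- pom_mean(0.006, 0.002, 12, aa_eqs = 0.006, assessed = "good")
  expect_equal(p$p_om, 0.5, tolerance = 1e-12)
})

test_that("pom_mean matches the quadrature oracle, truncated or not", {
  st <- series_stats(table2_series("bap"))
  p <- pom_mean(st$mean, st$stdev_modified, st$n, aa_eqs = 1.7e-4,
                assessed = "good")
  expect_equal(p$p_om, quad_pom_mean(st$mean, st$stdev_modified, 6, 1.7e-4),
               tolerance = 1e-8)
  pt_ <- pom_mean(st$mean, st$stdev_modified, st$n, aa_eqs = 1.7e-4,
                  assessed = "good", truncate = TRUE)
  expect_equal(pt_$p_om,
               quad_pom_mean(st$mean, st$stdev_modified, 6, 1.7e-4,
                             truncate = TRUE),
               tolerance = 1e-8)
  # truncation matters here because the mean is within two scales of zero
  expect_false(isTRUE(all.equal(p$p_om, pt_$p_om)))
})

test_that("criterion probabilities are complementary and sane", {
  withr::local_seed(23)
  for (rep in 1:100) {
    m <- runif(1, 0.001, 1)
    s <- runif(1, 0.0001, 1)
    n <- sample(2:24, 1)
    aa <- runif(1, 0.001, 1)
    assessed <- if (m > aa) "below_good" else "good"
    p <- pom_mean(m, s, n, aa, assessed = assessed)
    expect_equal(p$p_class + p$p_om, 1, tolerance = 1e-12)
    expect_gte(p$p_om, 0)
    expect_lte(p$p_om, 1)
  }
})

test_that("pom_mean grows with the spread and vanishes as it shrinks", {
  spreads <- 10^seq(-4, -1, length.out = 10)
  poms <- vapply(spreads, function(s) {
    pom_mean(0.003, s, 12, aa_eqs = 0.006, assessed = "good")$p_om
  }, 0)
  expect_true(all(diff(poms) > 0))
  expect_lt(poms[1], 1e-12)
})

test_that("pom_mean is symmetric about the threshold", {
  for (d in c(0.001, 0.01, 0.1)) {
    up <- pom_mean(1 + d, 0.5, 12, aa_eqs = 1, assessed = "below_good")
    dn <- pom_mean(1 - d, 0.5, 12, aa_eqs = 1, assessed = "good")
    expect_equal(up$p_om, dn$p_om, tolerance = 1e-12)
  }
})

test_that("inconsistent assessed class is a caller error", {
  expect_error(pom_mean(0.01, 0.001, 6, aa_eqs = 0.005, assessed = "good"),
               "exceeds AA-EQS")
  expect_error(pom_mean(0.001, 0.001, 6, aa_eqs = 0.005,
                        assessed = "below_good"), "does not exceed")
  expect_error(pom_mean(0.001, 0.001, 1, aa_eqs = 0.005, assessed = "good"),
               "n >= 2")
  st <- series_stats(table2_series("bap"))
  expect_error(pom_max(substituted_values(table2_series("bap")), st,
                       mac_eqs = 1e-4, assessed = "good"),
               "exceeds MAC-EQS")
})

test_that("the moments-fit Gumbel tail matches its quadrature oracle", {
  s <- table2_series("fluo")
  st <- series_stats(s)
  p <- pom_max(substituted_values(s), st, mac_eqs = 0.12,
               assessed = "good", fit_method = "moments",
               stdev_variant = "modified")
  expect_equal(p$p_om, quad_pom_max(st$mean, st$stdev_modified, 0.12),
               tolerance = 1e-8)
  # conventional variant feeds a different spread, hence a different P_om;
  # tested at a threshold near the observed maximum where the tails differ
  pm2 <- pom_max(substituted_values(s), st, mac_eqs = 0.01,
                 assessed = "good", stdev_variant = "modified")
  pc2 <- pom_max(substituted_values(s), st, mac_eqs = 0.01,
                 assessed = "good", stdev_variant = "conventional")
  expect_equal(pc2$p_om, quad_pom_max(st$mean, st$stdev_conventional, 0.01),
               tolerance = 1e-8)
  expect_gt(pm2$p_om, pc2$p_om)
})

test_that("degenerate spread yields a point mass for the maximum criterion", {
  s <- table2_series("endo")
  st <- series_stats(s)
  p <- pom_max(substituted_values(s), st, mac_eqs = 0.01,
               assessed = "good", stdev_variant = "conventional")
  expect_identical(p$p_om, 0)
  expect_warning(
    pmle <- pom_max(substituted_values(s), st, mac_eqs = 0.01,
                    assessed = "good", fit_method = "mle"),
    "point mass")
  expect_identical(pmle$p_om, 0)
})

test_that("a remote threshold makes max misclassification negligible", {
  s <- table2_series("fluo")
  st <- series_stats(s)
  p <- pom_max(substituted_values(s), st, mac_eqs = 1e6,
               assessed = "good")
  expect_lt(p$p_om, 1e-12)
})

test_that("the MLE Gumbel fit maximises the likelihood near the moments fit", {
  withr::local_seed(31)
  x <- 0.05 + 0.005 * (-log(-log(runif(50))))  # gumbel-ish sample
  s <- indicator_series("WB", "x", 2017L, values = x,
                        censored = rep(FALSE, 50))
  st <- series_stats(s)
  mac <- max(x) * 1.5
  p <- pom_max(substituted_values(s), st, mac_eqs = mac, assessed = "good",
               fit_method = "mle")
  expect_gt(p$p_om, 0)
  expect_lt(p$p_om, 1)
  # MLE and moments agree loosely on a clean Gumbel sample
  pm <- pom_max(substituted_values(s), st, mac_eqs = mac, assessed = "good",
                fit_method = "moments")
  expect_equal(p$p_om, pm$p_om, tolerance = 0.5)
})

test_that("level-3 composition follows the classification case", {
  cpom <- function(criterion, p) {
    pomstat:::criterion_pom(criterion, "good", 1 - p, p)
  }
  good <- good_class_fixture()
  # good class: the larger of the two criterion values
  expect_equal(indicator_pom(good, cpom("mean", 0.81), cpom("max", 0.16)),
               0.81)
  expect_equal(indicator_pom(good, cpom("mean", 0.20), cpom("max", 0.47)),
               0.47)
  # decisive single criteria
  ii <- good; ii$case <- "ii"
  iii <- good; iii$case <- "iii"
  iv <- good; iv$case <- "iv"
  expect_equal(indicator_pom(ii, cpom("mean", 0.3), cpom("max", 0.9)), 0.3)
  expect_equal(indicator_pom(iii, cpom("mean", 0.9), cpom("max", 0.25)),
               0.25)
  # both exceeded: simultaneous errors multiply
  expect_equal(indicator_pom(iv, cpom("mean", 0.3), cpom("max", 0.4)), 0.12)
  # the product never exceeds either factor
  withr::local_seed(37)
  for (rep in 1:50) {
    a <- runif(1); b <- runif(1)
    prod <- indicator_pom(iv, cpom("mean", a), cpom("max", b))
    expect_lte(prod, min(a, b))
  }
})
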