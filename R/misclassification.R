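# Euler-Mascheroni constant, mean of the standard Gumbel.
EULER_GAMMA <- 0.57721566490153286

# Right-hand (maximum) Gumbel type I distribution.
pgumbel <- function(q, location, scale) {
  exp(-exp(-(q - location) / scale))
}

dgumbel <- function(x, location, scale) {
  z <- (x - location) / scale
  exp(-z - exp(-z)) / scale
}

# Method-of-moments Gumbel fit: matches the sample mean and a standard
# deviation (either variant). Var = pi^2 beta^2 / 6, E = mu + gamma beta.
gumbel_moments_fit <- function(mean, stdev) {
  beta <- stdev * sqrt(6) / pi
  list(location = mean - EULER_GAMMA * beta, scale = beta)
}

# Maximum-likelihood Gumbel fit to the observed values, initialised at the
# moments fit. Degenerate samples (all values identical) have no MLE.
gumbel_mle_fit <- function(values) {
  if (stats::sd(values) == 0) {
    return(NULL)
  }
  init <- gumbel_moments_fit(mean(values), stats::sd(values))
  nll <- function(par) {
    if (par[2] <= 0) return(Inf)
    -sum(log(dgumbel(values, par[1], par[2])))
  }
  fit <- stats::optim(c(init$location, init$scale), nll,
                      method = "Nelder-Mead")
  list(location = fit$par[1], scale = fit$par[2])
}

criterion_pom <- function(criterion, assessed, p_class, p_om,
                          stdev_variant = NA_character_) {
  structure(
    list(criterion = criterion, assessed = assessed,
         p_class = p_class, p_om = p_om, stdev_variant = stdev_variant),
    class = "criterion_pom"
  )
}

#' @export
print.criterion_pom <- function(x, ...) {
  cat(sprintf("<criterion_pom> %s criterion, assessed %s: P(class) = %.4g, P_om = %.4g\n",
              x$criterion, x$assessed, x$p_class, x$p_om))
  invisible(x)
}

#' Misclassification probability of the mean criterion
#'
#' The annual mean is a random variable; its sampling distribution is
#' modelled as a Student t with `n - 1` degrees of freedom, located at the
#' observed mean with scale `stdev / sqrt(n)`. For a good-class indicator
#' the correct-class region of the mean is everything up to AA-EQS, so the
#' misclassification probability is the upper tail beyond the threshold;
#' for a below-good indicator (mean criterion decisive) it is the lower
#' tail. A zero standard deviation collapses the distribution to a point
#' mass at the mean and the misclassification probability to zero — the
#' degenerate behaviour that motivates the modified standard deviation for
#' heavily censored series.
#'
#' @param mean Observed annual mean (half-LOQ substituted), ug/l.
#' @param stdev Standard deviation of the observations (either variant),
#'   ug/l; the sampling scale `stdev/sqrt(n)` is formed internally.
#' @param n Number of observations, at least 2.
#' @param aa_eqs Annual-average threshold, ug/l.
#' @param assessed `"good"` or `"below_good"`: the verdict of the mean
#'   criterion itself (must be consistent with `mean` vs `aa_eqs`).
#' @param truncate If `TRUE`, the t distribution is renormalised over the
#'   non-negative half line before taking tail probabilities; the default
#'   keeps the untruncated distribution. The difference only matters when
#'   the mean is within about two scale units of zero.
#' @param stdev_variant Optional label (`"conventional"`/`"modified"`)
#'   recorded in the result.
#' @return A `"criterion_pom"` with fields `p_class` and `p_om`
#'   (`p_class + p_om = 1`).
#' @export
pom_mean <- function(mean, stdev, n, aa_eqs,
                     assessed = c("good", "below_good"),
                     truncate = FALSE, stdev_variant = NA_character_) {
  assessed <- match.arg(assessed)
  if (!is.finite(n) || n < 2) stop("pom_mean needs n >= 2", call. = FALSE)
  if (!is.finite(stdev) || stdev < 0) {
    stop("pom_mean needs a finite non-negative stdev", call. = FALSE)
  }
  stopifnot(is.finite(mean), is.finite(aa_eqs), aa_eqs > 0)
  mean_exceeds <- mean > aa_eqs
  if (mean_exceeds && assessed == "good") {
    stop("assessed 'good' but mean exceeds AA-EQS", call. = FALSE)
  }
  if (!mean_exceeds && assessed == "below_good") {
    stop("assessed 'below_good' but mean does not exceed AA-EQS",
         call. = FALSE)
  }
  if (stdev == 0) {
    return(criterion_pom("mean", assessed, 1, 0, stdev_variant))
  }
  scale <- stdev / sqrt(n)
  df <- n - 1
  F_aa <- stats::pt((aa_eqs - mean) / scale, df)
  if (truncate) {
    F_zero <- stats::pt((0 - mean) / scale, df)
    p_below <- (F_aa - F_zero) / (1 - F_zero)
  } else {
    p_below <- F_aa
  }
  p_om <- if (assessed == "good") 1 - p_below else p_below
  criterion_pom("mean", assessed, 1 - p_om, p_om, stdev_variant)
}

#' Misclassification probability of the maximum criterion
#'
#' The annual maximum is modelled with the right-hand Gumbel (type I
#' extreme-value) distribution. With `fit_method = "moments"` (the default)
#' the Gumbel is matched to the substituted-series mean and the selected
#' standard-deviation variant (`scale = stdev * sqrt(6) / pi`,
#' `location = mean - gamma * scale`); this is the only fit under which the
#' conventional/modified choice can change the max-criterion probability.
#' With `fit_method = "mle"` the Gumbel is fitted to the substituted values
#' by maximum likelihood. Zero spread degenerates to a point mass and a
#' zero misclassification probability (with a warning under `"mle"`).
#'
#' @param values Substituted concentrations of the series, used by the MLE
#'   fit; at least 2.
#' @param stats The [series_stats()] of the series (supplies the mean and
#'   the standard-deviation variants for the moments fit).
#' @param mac_eqs Maximum-allowable-concentration threshold, ug/l.
#' @param assessed `"good"` or `"below_good"`: the verdict of the maximum
#'   criterion itself (consistent with `stats$maximum` vs `mac_eqs`).
#' @param fit_method `"moments"` or `"mle"`.
#' @param stdev_variant Which standard deviation feeds the moments fit.
#' @return A `"criterion_pom"`.
#' @export
pom_max <- function(values, stats, mac_eqs,
                    assessed = c("good", "below_good"),
                    fit_method = c("moments", "mle"),
                    stdev_variant = c("modified", "conventional")) {
  assessed <- match.arg(assessed)
  fit_method <- match.arg(fit_method)
  stdev_variant <- match.arg(stdev_variant)
  stopifnot(inherits(stats, "series_stats"),
            is.finite(mac_eqs), mac_eqs > 0, length(values) >= 2L)
  max_exceeds <- stats$maximum > mac_eqs
  if (max_exceeds && assessed == "good") {
    stop("assessed 'good' but maximum exceeds MAC-EQS", call. = FALSE)
  }
  if (!max_exceeds && assessed == "below_good") {
    stop("assessed 'below_good' but maximum does not exceed MAC-EQS",
         call. = FALSE)
  }
  if (fit_method == "moments") {
    s <- stdev_for_variant(stats, stdev_variant)
    if (is.na(s)) stop("stdev unavailable (n < 2)", call. = FALSE)
    fit <- if (s == 0) NULL else gumbel_moments_fit(stats$mean, s)
  } else {
    fit <- gumbel_mle_fit(values)
    if (is.null(fit)) {
      warning("all values identical; Gumbel MLE undefined, ",
              "falling back to a point mass", call. = FALSE)
    }
  }
  if (is.null(fit)) {
    return(criterion_pom("max", assessed, 1, 0, stdev_variant))
  }
  p_below <- pgumbel(mac_eqs, fit$location, fit$scale)
  p_om <- if (assessed == "good") 1 - p_below else p_below
  criterion_pom("max", assessed, 1 - p_om, p_om, stdev_variant)
}

#' Level-3 misclassification probability of one indicator
#'
#' Combines the two criterion-level probabilities into the single
#' per-indicator value of the hierarchy, according to the classification
#' case:
#'
#' * case i (good): the larger of the two criterion probabilities;
#' * case ii (mean decisive): the mean-criterion probability;
#' * case iii (maximum decisive): the max-criterion probability;
#' * case iv (both exceeded): the product of the two — misclassification
#'   requires both criteria to be wrong simultaneously.
#'
#' @param cls An `"indicator_class"`.
#' @param pm The mean-criterion `"criterion_pom"`.
#' @param px The max-criterion `"criterion_pom"`.
#' @return A single probability.
#' @export
indicator_pom <- function(cls, pm, px) {
  stopifnot(inherits(cls, "indicator_class"),
            inherits(pm, "criterion_pom"), pm$criterion == "mean",
            inherits(px, "criterion_pom"), px$criterion == "max")
  switch(cls$case,
         i = max(pm$p_om, px$p_om),
         ii = pm$p_om,
         iii = px$p_om,
         iv = pm$p_om * px$p_om)
}
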