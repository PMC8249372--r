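---
title: "Misclassification probability of chemical status from censored monitoring series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Misclassification probability of chemical status from censored monitoring series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pomstat)
```

## The problem

Under the Water Framework Directive every surface-water body receives a
binary chemical status — *good* or *below good* — from annual monitoring
series of priority-substance concentrations. An indicator is good only when
its annual mean stays at or below the annual-average standard (AA-EQS) *and*
its maximum stays at or below the maximum-allowable standard (MAC-EQS); one
failing indicator downgrades the whole water body (one-out-all-out, OOAO).

Both the mean and the maximum are random realisations of a noisy monitoring
process, so every classification carries a probability of misclassification,
P_om: the probability that the assigned class differs from the true one.
pomstat computes this probability per criterion, per indicator and per water
body.

The complication this package exists for is left-censoring. Many priority
substances sit near or below the laboratory limit of quantification (LOQ).
The regulatory rule (Directive 2009/90/EC) replaces each censored reading by
half the LOQ before averaging. A series reported entirely below the LOQ then
becomes a constant, its sample standard deviation is exactly zero, and any
spread-based uncertainty measure concludes the classification is *perfect* —
the more censoring, the more (spuriously) certain the status. That is
backwards: a censored reading could be anything between zero and the LOQ.

## The model

### Summary statistics under censoring

For a series \(x_1,\dots,x_n\) with censored readings substituted at
LOQ/2, [series_stats()] returns the mean \(\bar{x}\), the maximum, the
conventional sample standard deviation (divisor \(n-1\)), and a **modified
standard deviation** in which each censored observation contributes the
value 0 while deviations are still taken from the substituted mean:

\[
s_{\mathrm{mod}} \;=\; \sqrt{\tfrac{1}{n-1}\textstyle\sum_i (x_i^{0} - \bar{x})^2},
\qquad
x_i^{0} = \begin{cases} 0 & x_i \text{ censored} \\ x_i & \text{otherwise.} \end{cases}
\]

Setting the censored value to zero maximises its distance from LOQ/2 (using
the LOQ itself would give the same distance), so a fully censored series of
\(n\) readings at a common LOQ \(L\) retains the positive spread
\(\sqrt{n/(n-1)}\,L/2\) instead of collapsing to zero. With no censoring the
two formulas coincide exactly.

A note on the divisor: the defining formula for the modified standard
deviation is sometimes quoted with divisor \(1/N\), but the worked numerical
example it comes with, and every tabulated value we reproduce, use
\(1/(N-1)\). This package implements \(n-1\) throughout and treats the
\(1/N\) spelling as an erratum.

### Criterion-level P_om

**Mean criterion.** The sampling distribution of the annual mean is modelled
as Student's t with \(n-1\) degrees of freedom, located at \(\bar{x}\) with
scale \(s/\sqrt{n}\) (the moment identities \(E(\bar{x}) = E(x)\) and
\(\sigma(\bar{x}) = \sigma(x)/\sqrt{n}\)). For a good-class indicator the
correct-class region of the mean is everything up to AA-EQS, so

\[ P_{om} = 1 - F_t(\mathrm{AA\text{-}EQS}), \]

and symmetrically the lower tail when the mean criterion is decisive for a
below-good class. Measurement bias is assumed zero. Degrees of freedom
\(n-1\) is the standard small-sample choice; it is not separately
prescribed by the source method description.

**Support truncation.** Concentrations are non-negative but the class
interval's lower limit is not prescribed. By default the t distribution is
left untruncated (lower limit \(-\infty\)); `truncate = TRUE` renormalises
it over \([0,\infty)\). The difference is negligible unless the mean lies
within about two scale units of zero — which does happen for heavily
censored series, so both modes are exposed and tested.

**Maximum criterion.** The annual maximum is modelled with the right-hand
Gumbel (type I extreme-value) distribution. The default fit is by moments
from the substituted-series mean and the *selected* standard-deviation
variant (\(\beta = s\sqrt{6}/\pi\), \(\mu = \bar{x} - \gamma\beta\) with
\(\gamma\) the Euler–Mascheroni constant). This is the reading under which
the conventional/modified choice propagates to the max criterion, matching
the tabulated behaviour of the worked examples; an MLE fit to the
substituted values is available as `fit_method = "mle"` (hand-implemented
via `stats::optim`; a degenerate all-equal sample falls back to a point
mass with a warning). Zero spread yields \(P_{om} = 0\) under either
method.

### The four-level hierarchy

* **Level 1** — indicators classified good/below good (cases i–iv).
* **Level 2** — per indicator, the two criterion P_oms.
* **Level 3** — one P_om per indicator: case i takes the larger of the two;
  cases ii and iii take the decisive criterion's value; case iv, where both
  thresholds are exceeded, takes the *product* (misclassifying the status
  requires both criteria to be wrong at once).
* **Level 4** — the status P_om: the largest Level-3 value over all
  indicators for a good-status water body, and over the decisive
  (below-good) indicators only otherwise, since good indicators are not
  decisive under OOAO. Ties break to the lexicographically smallest
  indicator id so reports are deterministic.

For a below-good water body with several decisive indicators, taking the
highest Level-3 value is the stated rule and is what we implement; a
joint-error product across decisive indicators would be probabilistically
arguable but is not the described procedure.

Status P_om values are reported in four intervals, read as a partition of
\([0,1]\): \([0,0.1]\), \((0.1,0.3]\), \((0.3,0.5]\), \((0.5,1]\) — the
first closed, the rest half-open, following the punctuation of the source
notation.

## Worked example

The three printed lacustrine series (two quantified readings of
benzo(a)pyrene, three of fluoranthene, endosulfan entirely censored):

```{r}
meas <- data.frame(
  wb_id = rep(c("PLLW10035", "PLLW10051", "PLLW10015"), each = 6),
  indicator = rep(c("benzo(a)pyrene", "fluoranthene", "endosulfan"), each = 6),
  year = 2017L,
  value = c("<0.00005", "0.0008", "0.00008", "<0.00005", "<0.00005", "<0.00005",
            "0.009", "0.003", "<0.001", "<0.001", "0.007", "<0.001",
            rep("< 0.001", 6)))
eqs <- data.frame(
  indicator = c("benzo(a)pyrene", "fluoranthene", "endosulfan"),
  aa_eqs = c(1.7e-4, 0.006, 0.005), mac_eqs = c(0.27, 0.12, 0.01))
res <- assess(meas, eqs, stdev_variant = "both")
res$indicators[, c("indicator", "stdev_variant", "mean", "maximum",
                   "stdev", "case", "pom_mean", "pom_max", "level3")]
```

All three indicators are good (case i). The all-censored endosulfan series
shows the pathology and its remedy: under the conventional standard
deviation its P_om is exactly 0 — a physically implausible claim of perfect
certainty — while the modified variant keeps a positive spread and a
positive P_om.

Note that the probabilities printed by this package follow the t/Gumbel
construction described above at full precision; they are what the stated
model yields for these inputs. (The tabulated probability cells of the
source worked examples are not reproducible from that construction and are
not used as references; the statistics rows and the Level-3 composition
rule are.)

## The synthetic-data generator

Real national monitoring databases are not public, so the package ships a
generator ([generate_monitoring()]) stating a transparent world: per (water
body, indicator, year), `n_per_year` independent draws from a lognormal
concentration distribution, reported as censored tokens below the
indicator's LOQ, with a truth table carrying the true mean and true class.
Defaults and the reasons for them:

* **lognormal truth** — the standard positive-support model for
  micro-pollutant concentrations, which show considerable variance in
  practice; a degenerate `sdlog = 0` option exists for edge cases;
* **`n_per_year = 12`** — the Directive's minimum (monthly) monitoring
  frequency;
* **`sdlog = 0.5`** (coefficient of variation ≈ 53%) and a default true
  mean of 0.8 × AA-EQS in [example_indicators()] — annual series near the
  threshold with moderate-to-high relative spread, the regime where
  misclassification actually matters;
* **true class for the maximum criterion** — the truth table flags MAC
  exceedance when the *median annual maximum* (the \(0.5^{1/n}\) quantile
  of the concentration distribution) exceeds MAC-EQS; the true mean is
  compared to AA-EQS directly.

What the generator does **not** emulate: temporal autocorrelation,
seasonality, inter-indicator correlation (deliberately not modelled
anywhere in this method — correlations between substances are ignored),
measurement bias, or heterogeneous LOQs within a year. A green calibration
test therefore establishes that the probability model is self-consistent
under independence, not that real series are independent.

[recovery_experiment()] closes the loop: it generates a cohort, runs the
full assessment, joins the truth, and reports the empirical
misclassification frequency overall and within each P_om bin. In the
package's acceptance suite a cohort with its true mean exactly at AA-EQS is
misclassified about half the time (0.5 ± 0.05 over 1000 seeded
replicates), and a varied-truth cohort shows empirical error frequencies
increasing across the P_om bins.

## Numerical and design choices

* Thresholds are read strictly: a mean exactly equal to AA-EQS is good.
* The maximum is taken over substituted values, so an all-censored series
  has maximum LOQ/2.
* Heterogeneous LOQs within a series are allowed; each censored value uses
  its own LOQ/2 (and contributes its own 0 to the modified formula).
* The pesticide sum rule (aldrin/dieldrin/endrin/isodrin) sums the
  members' substituted values per sampling date and classifies the summed
  series against the group threshold; whether the rule should use per-date
  sums or a sum of annual means is not prescribed — per-date summation is
  implemented because it commutes with taking the annual mean and also
  defines a maximum for the MAC criterion. Members of a sum group are
  assessed only through their group.
* Series with a single observation are classified but carry `NA`
  probabilities and are excluded from Levels 3–4.
* Probabilities and statistics are kept at full precision; rounding (e.g.
  two significant figures for display) happens only in rendering.
* All randomness in the generator is governed by a single integer seed and
  the caller's RNG state is restored afterwards.

## Limitations

* P_om is a within-series, distribution-model uncertainty; sampling design
  effects, laboratory bias and spatial heterogeneity are outside the model.
* The substitution scheme is the regulatory one; Kaplan–Meier,
  regression-on-order-statistics or censored-MLE estimators are deliberately
  out of scope.
* Correlation between indicators is ignored, which tends to make the OOAO
  maximum at Level 4 conservative.
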