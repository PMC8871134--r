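---
title: "Joint modeling of gestational weight gain and infant birth weight"
author: "gwjoint"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint modeling of gestational weight gain and infant birth weight}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Pregnancy cohorts record maternal weight sparsely and irregularly: a
self-reported pregravid weight at recruitment, then clinical measurements
at prenatal visits whose timing and number differ across women. A common
question is how the *rate* of weight gain in different gestational periods
relates to a scalar outcome such as infant birth weight. The widespread
two-stage answer — average the weights falling in each gestational
interval, convert adjacent averages into per-interval rates, and regress
the outcome on those precomputed rates — ignores the timing of individual
measurements, uses only a handful of observations per feature, and passes
all of their noise (and any self-report bias in the pregravid anchor)
straight into the regression, where it attenuates the estimated effects
toward zero.

`gwjoint` implements a hierarchical Bayesian joint model that avoids the
precomputation entirely, together with that two-stage comparator, a
synthetic-cohort generator, and the diagnostics needed to study both.

## The model

For woman $i$ with weights $X_{ij}$ (kg) at gestational ages $t_{ij}$
(weeks):

$$X_{ij} = f(t_{ij}; b_i) + \varepsilon_{ij}, \qquad
  \varepsilon_{ij} \sim N(0, \sigma^2_i), \qquad
  b_i \sim N(\beta, \Sigma),$$

where $f(t; b) = b_0 + \sum_{k=1}^K b_k (t - t^*_k)_+$ is a linear spline
with knots $t^*_1 = 0 < t^*_2 < \dots < t^*_K$. Thus $b_0$ is the
pregravid weight, $b_k$ is the change in the weekly gain rate at knot $k$,
and the mean rate on $[t^*_k, t^*_{k+1})$ is the partial sum
$\sum_{j \le k} b_j$. The default knots are
$0, 13, 18, 23, 27, 32, 37, 45$ weeks ($K = 8$), aligned with trimester
boundaries; an alternative grid $0, 15, 20, 25, 30, 35, 45$ is provided
for sensitivity analysis. The log residual variances are themselves random
effects, $\ln \sigma^2_i \sim N(\mu, \tau^2)$.

Birth weight is regressed on the subject-specific trajectory parameters:

$$Y_i = (1,\, z_i^\top,\, b_i^\top,\, \ln\sigma^2_i)\,\theta +
  \epsilon_i, \qquad \epsilon_i \sim N(0, \sigma^2),$$

with $z_i$ the treatment-coded demographics. Because $b_i$ and
$\ln\sigma^2_i$ are latent, estimation is joint: the outcome borrows
strength from every weight measurement, and a biased week-0 self-report
is shrunk toward what the clinical measurements imply rather than taken
at face value. The week-0 self-report enters the longitudinal design as an
ordinary observation at $t = 0$ (configurable); with clinical observations
present, shrinkage through the shared trajectory model is the mechanism
that corrects self-report bias.

### Priors

Diffuse defaults: $\theta \sim N(0, 10 I)$, $\beta \sim N(0, c I)$,
$\sigma^2, \tau^2 \sim \text{Inv-Gamma}(10^{-4}, 10^{-4})$ (shape/rate),
$\mu \sim N(0, 10^3)$. The random-effect covariance gets an
empirical-Bayes Wishart prior
$\Sigma \sim W\!\left(m, \Lambda\right)$ with
$\Lambda = \sum_i \widehat{\text{Cov}}(\hat b_i^{OLS})^{-1}$ assembled
from per-subject ordinary-least-squares fits, each inverse computed on the
subject's identifiable columns (a subject contributes no precision on
hinge columns it never observes past). We default the degrees of freedom
to $m = K + 3$ — dimension plus two, the smallest standard
weakly-informative choice that keeps the density proper — and expose
both $m$ and two parses of the $\Lambda$ sum (`sum_of_inverses`, the
literal reading, and `inverse_of_sum`) plus an optional $1/n$
normalization in the configuration, since reasonable readers can differ
on all three. A conjugate inverse-Wishart mode is available as a fallback
parameterization.

Two deliberate scale choices deserve note. First, the terminal hinge
(knot at 45 weeks) has no observations beyond it in any realistic cohort;
its $\Lambda$ diagonal receives no data contribution and is filled so
that the implied prior mean of that variance component equals the pooled
per-subject OLS variance of the identified slope components. The
component is retained and reported as prior-dominated. Second,
$N(0, 10)$ is diffuse for effects near zero but is *informative* for a
pregravid intercept near 65 kg: at moderate cohort sizes it shrinks
$\beta_0$ by a couple of kilograms. The package therefore keeps 10 as the
conventional default but uses — and recommends — `beta_var = 1e4` when
the data are kept in original units, as all worked examples and the
acceptance studies do.

### Sampling

A systematic-scan Gibbs sampler updates, in order: all $b_i$ (exact
Gaussian full conditionals), all $\ln\sigma^2_i$, $\beta$, $\Sigma$,
$(\mu, \tau^2)$, and $(\theta, \sigma^2)$ — the conjugate blocks from
their closed forms. Two blocks need care:

* **$\ln\sigma^2_i$** has no closed form (it appears in the longitudinal
  variance, its own log-normal prior, and the outcome mean). Its log
  conditional is strictly concave, so the mode is found by Newton's
  method; the density is evaluated on a uniform grid spanning
  mode $\pm \max(8\tau, 10)$ (2048 points by default, configurable down
  to 64), and a draw is made by inverting the discrete CDF with
  within-cell linear interpolation. Tests verify the grid's first two
  moments against adaptive quadrature and the draws against the grid CDF
  by a Kolmogorov–Smirnov distance.
* **$\Sigma$** under the Wishart-on-covariance prior has conditional
  density $\propto |\Sigma|^{(m-K-2-n)/2}
  \exp\{-\tfrac12 \mathrm{tr}(\Lambda^{-1}\Sigma)
  -\tfrac12 \mathrm{tr}(\Sigma^{-1}S)\}$, which is not a standard family.
  It is advanced by an independence Metropolis step with proposal
  $IW(\max(n - m, K + 3),\, S)$, chosen because that kernel matches the
  inverse-Wishart-shaped part of the target exactly: the log acceptance
  ratio collapses to the bounded difference
  $-\tfrac12\mathrm{tr}\{\Lambda^{-1}(\Sigma^* - \Sigma)\}$, so
  acceptance is near one whenever the Wishart factor is mild relative to
  the random-effect scatter, degrades gracefully when it is not, and the
  chain can never stick at an extreme state. Acceptance rates are logged;
  they sit around 0.6–0.9 in the regimes the tests exercise. The
  conjugate inverse-Wishart mode draws its exact conditional instead.

Defaults follow the standard settings: 150,000 iterations, the first
50,000 discarded, every 10th retained, five chains (so 10,000 retained
draws per chain). The model mixes quickly, and a fast preset (10,000
total iterations, half burned) is provided and used throughout the
simulation studies. Chains are seeded `seed + chain - 1` and all
randomness — including the compiled core, which calls R's RNG — replays
bit-identically under a fixed seed.

Initialization is from per-subject OLS (ridge-stabilized for sparse
subjects, population-mean fallback for unidentifiable columns), residual
variances floored at $10^{-4}$, and a ridge least-squares fit for
$\theta$; this shortens burn-in but is not load-bearing for correctness.

## The two-stage comparator

`fit_lr()` reproduces the traditional pipeline: interval means
$\mu_k$ over $[0,13), [13,18), [18,23), [23,27), [27,32), [32,37),
[37,45)$ (half-open; week-0 measurements define $\mu_0$), midpoint rates
$\tilde b_k = (\mu_k - \mu_{k-1})/(m_k - m_{k-1})$ with midpoints
$6.5, 15.5, 20.5, 25, 29.5, 34.5, 41$ and $m_0 = 0$, then OLS of $Y$ on
demographics, $\tilde b_0$, and $\tilde b_1 \dots \tilde b_7$ with
classical $t$ intervals. Subjects missing any rate feature are dropped
(complete-case; an empty interval gives no rate), matching standard
regression software; this is itself one of the method's practical
weaknesses on sparse designs. The reduced models (second-stage variants)
share one pruning rule: drop exactly the demographic covariates whose 95%
interval in the first fit contains zero — a categorical covariate
survives if any level excludes zero — and always keep the
pregravid-weight, rate, and residual-variance predictors.

## Reporting

Rate effects are reported per gestational interval as the cumulative sums
$\sum_{j \le k} \theta_{b_j}$, $k = 1, \dots, K-1$ (the terminal slope
change, supported by no data, is excluded). An alternative `"difference"`
mode reports $\theta_{b_k} - \theta_{b_{k+1}}$, which under the
slope-change parameterization is the marginal effect of raising only
interval $k$'s rate; both are exposed because the two transforms answer
subtly different questions, and the cumulative form is the conventional
presentation. Intervals are equal-tailed empirical quantiles (type-7,
linear interpolation); convergence is summarized by the classic
Gelman–Rubin potential scale reduction factor
$\sqrt{\hat V / W}$ with $\hat V = \frac{n-1}{n} W + B/n$, computed per
parameter on thinned post-burn-in draws.

## The synthetic cohort generator

Real cohorts of this kind are access-restricted, so `simulate_cohort()`
generates data with the structure every stage needs: recruitment split
between an early class (measurements in all three trimesters, default
70%) and a late class (nothing before week 14); clinical visit ages in
4.4–41.7 weeks, capped at a truncated-normal delivery age
($N(39.5, 1.5^2)$ on $[30, 42]$); visit counts $3 + \text{Poisson}(9)$,
shifted so every subject clears the three-measurement inclusion rule and
calibrated to a median of 12; a week-0 self-report with configurable bias
(mean and SD in kg, default none); and categorical demographics drawn
from marginal frequencies matching a contemporary Canadian pregnancy
cohort (≈97% married, ≈83% Caucasian, ≈20% income below \$70k, parity
0/1/2+ ≈ 56/34/10%), treatment-coded identically to the file reader so
generated and read cohorts are interchangeable.

The default generative truth is fixed once, on domain grounds: pregravid
weight $N(65, 12^2)$ kg; mean gain rates 0.25 kg/wk in the first
trimester rising to 0.50 mid-pregnancy and easing to 0.40 near term
(total gain ≈ 13.5 kg); between-woman rate-increment SDs of 0.12
(first slope) and 0.06 kg/wk, giving a realistic ≈5 kg SD of total gain;
$\ln\sigma^2_i \sim N(2\ln 0.9, 0.25)$ (median within-woman residual SD
0.9 kg); outcome effects following the cumulative profile
$0.70, 1.26, 1.70, 1.93, 2.01, 2.01, 2.03$ kg per kg/wk across the seven
intervals, 0.007 kg/kg on pregravid weight, small demographic effects,
and outcome residual SD 0.4 kg. Both profiles are step functions of
gestational age, so the same truth transfers coherently to alternative
knot grids.

What the generator does **not** emulate: scheduled-visit clustering and
missed-appointment patterns (visit times are uniform within class
constraints), joint dependence among demographics (marginals only),
covariate-dependent trajectories, or postpartum measurements. Passing
tests therefore demonstrate correctness of the machinery under the
model's own assumptions — not robustness to real-data phenomena such as
informative visit timing.

## Numerical choices and degenerate inputs

* Half-open interval convention everywhere: a measurement exactly at a
  knot or boundary belongs to the right interval; the hinge at its own
  knot is 0.
* Per-subject OLS drops structurally zero columns rather than
  regularizing (a configurable ridge, default 0, exists for near-singular
  Grams); the covariance estimate is embedded with zero rows/columns so
  precision sums stay well-defined.
* The $\ln\sigma^2_i$ grid recenters once on the prior mean if all masses
  underflow, then errors; small Cholesky factorizations retry once with a
  scaled jitter before raising an error naming the sampler block.
* Sums of squares are clamped at zero against cancellation in the
  $X^\top X - 2b^\top h + b^\top G b$ form.

## Problem sizes in the shipped studies

The test-suite and acceptance-script studies use: micro chains
(12 subjects, single-knot basis) for calibration ranks, 200 replicates;
recovery at $n = 400$ with the fast preset and a 256-point variance grid,
25 replicates in the tests and 5 in the script; attenuation at $n = 150$
with all-early recruitment and ≈14 visits (≈2 per interval), bias
$+2 \pm 2$ kg; knot-robustness refits on an $n = 400$ cohort with 30,000
iterations; and a five-chain convergence run at $n = 200$, also at
30,000 iterations, diagnosing the reported coefficients. These sizes are the package's chosen design points for
demonstrating the properties at desk scale; all of them are plain
arguments, so larger studies are a configuration change.

## Known limitations

* The rate effects $\theta_b$ act on latent slope increments whose
  between-woman variation is small; at a few hundred subjects their
  posteriors are honest but wide, and the cumulative-effect intervals
  can span zero even when the point estimates track the truth.
* The empirical-Bayes scale $\Lambda$ reuses the data that the likelihood
  then sees again; at the cohort sizes studied here the likelihood
  dominates for every identified component, but the double use is
  inherent to the construction.
* The independence Metropolis step for $\Sigma$ can mix slowly if the
  prior scale conflicts severely with the random-effect scatter;
  acceptance is logged so such runs are visible, and the conjugate
  inverse-Wishart mode is the escape hatch.
* Ordinal outcomes, Gaussian-mixture random effects, and data-driven knot
  selection are out of scope.
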