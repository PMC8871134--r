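#' Canonical weight-gain rate profile used by the synthetic generator
#'
#' Step function of gestational age giving the population mean rate of
#' weight gain (kg/week): slow gain through the first trimester, peak gain
#' mid-pregnancy, tapering toward term.
#' @param t Gestational ages (weeks).
#' @return Rates (kg/week).
#' @keywords internal
true_rate_profile <- function(t) {
  bounds <- c(0, 13, 18, 27, 32, 37)
  rates <- c(0.25, 0.45, 0.50, 0.50, 0.45, 0.40)
  rates[findInterval(t, bounds)]
}

#' Canonical cumulative rate-effect profile used by the synthetic generator
#'
#' Step function giving the true effect on birth weight (kg per kg/week) of
#' the weight-gain rate in the interval containing `t`: rising through
#' mid-pregnancy and flattening near term.
#' @param t Gestational ages (weeks).
#' @return Effects (kg per kg/week).
#' @keywords internal
true_effect_profile <- function(t) {
  bounds <- c(0, 13, 18, 23, 27, 32, 37)
  eff <- c(0.70, 1.26, 1.70, 1.93, 2.01, 2.01, 2.03)
  eff[findInterval(t, bounds)]
}

default_covariate_freq <- function() {
  list(marital_status = c(Married = 0.966, Single = 0.034),
       education = c("Some post-secondary" = 0.668,
                     "Graduate degree" = 0.232, "High school" = 0.100),
       income = c(">=70k" = 0.803, "<70k" = 0.197),
       ethnicity = c(Caucasian = 0.8262, Asian = 0.0634, Black = 0.0112,
                     "Latin American" = 0.0313, "Southeast Asian" = 0.0440,
                     Other = 0.0239),
       parity = c("0" = 0.560, "1" = 0.341, "2+" = 0.099))
}

default_theta_z <- function() {
  c("marital_statusSingle" = 0.151,
    "educationGraduate degree" = 0.016,
    "educationHigh school" = -0.034,
    "income<70k" = -0.039,
    "ethnicityAsian" = -0.038,
    "ethnicityBlack" = -0.322,
    "ethnicityLatin American" = -0.038,
    "ethnicitySoutheast Asian" = -0.098,
    "ethnicityOther" = -0.090,
    "parity1" = 0.147,
    "parity2+" = 0.246,
    "age_years" = -0.013,
    "ga_delivery_weeks" = 0.162)
}

#' Synthetic cohort configuration
#'
#' Defines the generative truth and sampling design of a synthetic
#' pregnancy cohort: subject-specific piecewise-linear weight trajectories
#' observed at irregular clinical visits, a week-0 self-reported pregravid
#' weight with optional reporting bias, demographic covariates drawn from
#' configurable marginal frequencies, and a birth-weight outcome generated
#' from the joint model.
#'
#' Trajectory and effect defaults are derived from canonical step profiles
#' so that they adapt to any changepoint grid: the population mean rate on
#' an interval is the profile value at its left endpoint, and likewise for
#' the cumulative outcome effects.
#'
#' @param n Subject count.
#' @param grid A [changepoint_grid()].
#' @param beta True mean trajectory (length K+1); default pregravid mean
#'   65 kg with the canonical rate profile.
#' @param Sigma True random-effect covariance; default diagonal with
#'   pregravid SD 12 kg and rate-increment SDs of 0.12 (first slope) /
#'   0.06 kg/week.
#' @param mu,tau2 Mean and variance of `ln sigma_i^2`; defaults give a
#'   median within-subject residual SD of 0.9 kg with moderate spread.
#' @param theta_b True outcome effects of `(b_0, ..., b_K)`; default
#'   0.007 kg/kg on pregravid weight and increments of the canonical
#'   effect profile on the rates.
#' @param theta_z Named true demographic effects, matched to the
#'   treatment-coded design columns (unmatched columns get 0).
#' @param theta0 Outcome intercept (kg); the default centers mean birth
#'   weight near 3.35 kg under the other defaults.
#' @param theta_v True effect of `ln sigma_i^2` on birth weight.
#' @param sigma2 Outcome residual variance (kg^2).
#' @param early_frac Fraction recruited before 13 weeks (measurements in
#'   all three trimesters); the rest are recruited at 14-27 weeks and have
#'   no clinical measurements before week 14.
#' @param visit_lambda Poisson mean of the shifted visit-count distribution
#'   `3 + Poisson(visit_lambda)`; the default 9 targets a median of 12
#'   visits.
#' @param visit_range Clinical-visit gestational age range (weeks).
#' @param selfreport_bias_mean,selfreport_bias_sd Bias and noise (kg) added
#'   to the week-0 self-reported pregravid weight.
#' @param include_selfreport Emit the week-0 self-report row.
#' @param covariate_freq Marginal frequency tables for the categorical
#'   covariates.
#' @param age_mean,age_sd Maternal age distribution (years).
#' @param delivery_mean,delivery_sd,delivery_range Gestational age at
#'   delivery: normal, truncated to `delivery_range`. Visits after
#'   delivery are not generated.
#' @param seed Optional RNG seed applied inside [simulate_cohort()].
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n = 400, grid = changepoint_grid(),
                         beta = NULL, Sigma = NULL,
                         mu = 2 * log(0.9), tau2 = 0.25,
                         theta_b = NULL, theta_z = default_theta_z(),
                         theta0 = -3.47, theta_v = 0.05, sigma2 = 0.16,
                         early_frac = 0.7, visit_lambda = 9,
                         visit_range = c(4.4, 41.7),
                         selfreport_bias_mean = 0, selfreport_bias_sd = 0,
                         include_selfreport = TRUE,
                         covariate_freq = default_covariate_freq(),
                         age_mean = 31.4, age_sd = 4.3,
                         delivery_mean = 39.5, delivery_sd = 1.5,
                         delivery_range = c(30, 42),
                         seed = NULL) {
  stopifnot(inherits(grid, "changepoint_grid"), n >= 1,
            early_frac >= 0, early_frac <= 1,
            selfreport_bias_sd >= 0, tau2 >= 0, sigma2 > 0)
  p <- grid$K + 1L
  if (is.null(beta)) {
    rates <- true_rate_profile(grid$knots)  # rate on [t_k, t_{k+1}) per knot
    beta <- c(65, slope_increments(rates))
  }
  if (is.null(Sigma)) {
    sds <- c(12, 0.12, rep(0.06, grid$K - 1L))
    Sigma <- diag(sds^2)
  }
  if (is.null(theta_b)) {
    eff <- true_effect_profile(grid$knots)
    theta_b <- c(0.007, slope_increments(eff))
  }
  stopifnot(length(beta) == p, all(dim(as.matrix(Sigma)) == p),
            length(theta_b) == p)
  structure(list(n = as.integer(n), grid = grid, beta = as.numeric(beta),
                 Sigma = as.matrix(Sigma), mu = mu, tau2 = tau2,
                 theta_b = as.numeric(theta_b), theta_z = theta_z,
                 theta0 = theta0, theta_v = theta_v, sigma2 = sigma2,
                 early_frac = early_frac, visit_lambda = visit_lambda,
                 visit_range = visit_range,
                 selfreport_bias_mean = selfreport_bias_mean,
                 selfreport_bias_sd = selfreport_bias_sd,
                 include_selfreport = include_selfreport,
                 covariate_freq = covariate_freq,
                 age_mean = age_mean, age_sd = age_sd,
                 delivery_mean = delivery_mean, delivery_sd = delivery_sd,
                 delivery_range = delivery_range, seed = seed),
            class = "synth_config")
}

rtruncnorm1 <- function(n, mean, sd, lower, upper) {
  x <- stats::rnorm(n, mean, sd)
  while (any(bad <- (x < lower | x > upper)))
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
  x
}

#' Sample clinical visit times for one subject
#'
#' Early recruits (< 13 weeks) get at least one visit in each trimester
#' band (first/second/third); late recruits (14-27 weeks) have no visits
#' before week 14. All times fall inside the configured range, capped at
#' delivery.
#'
#' @param class `"early"` or `"late"`.
#' @param n_visits Number of clinical visits (>= 3 for early subjects to
#'   honor the per-trimester guarantee).
#' @param upper Upper bound on visit age (min of range upper bound and
#'   delivery age).
#' @param config A [synth_config()].
#' @return Sorted visit gestational ages (weeks).
#' @export
sample_visit_times <- function(class = c("early", "late"), n_visits, upper,
                               config = synth_config()) {
  class <- match.arg(class)
  lo <- config$visit_range[1L]
  upper <- min(upper, config$visit_range[2L])
  if (class == "early") {
    t3_lo <- min(28, upper - 1e-6)
    base <- c(stats::runif(1, lo, 13), stats::runif(1, 14, min(27, upper)),
              stats::runif(1, t3_lo, upper))
    extra <- if (n_visits > 3L) stats::runif(n_visits - 3L, lo, upper)
             else numeric(0)
    times <- c(base[seq_len(min(3L, n_visits))], extra)
  } else {
    times <- stats::runif(n_visits, 14, upper)
  }
  sort(times)
}

#' Simulate a synthetic cohort
#'
#' Generates subject covariates from the configured marginal frequencies,
#' trajectory random effects `b_i ~ N(beta, Sigma)` and residual variances
#' `ln sigma_i^2 ~ N(mu, tau2)`, irregular clinical visit times by
#' recruitment class, noisy weight observations
#' `X_ij = f(t_ij; b_i) + N(0, sigma_i^2)`, a week-0 self-reported
#' pregravid weight `f(0; b_i) + bias + N(0, sd^2)`, and the birth-weight
#' outcome from the joint model. All latent values are recorded in the
#' truth ledger.
#'
#' @param config A [synth_config()].
#' @return A `gwg_cohort` whose `truth` element holds the per-subject
#'   effects (`effects` data frame) and the true parameters (`params`).
#' @export
simulate_cohort <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  if (!is.null(config$seed)) set.seed(as.integer(config$seed))
  n <- config$n; grid <- config$grid; p <- grid$K + 1L
  lv <- covariate_levels()
  freq <- config$covariate_freq
  subjects <- data.frame(subject_id = sprintf("S%04d", seq_len(n)))
  for (nm in names(freq)) {
    pr <- freq[[nm]]
    subjects[[nm]] <- factor(sample(names(pr), n, replace = TRUE, prob = pr),
                             levels = lv[[nm]])
  }
  subjects$age_years <- round(rtruncnorm1(n, config$age_mean, config$age_sd,
                                          16, 48), 1)
  subjects$ga_delivery_weeks <- round(
    rtruncnorm1(n, config$delivery_mean, config$delivery_sd,
                config$delivery_range[1L], config$delivery_range[2L]), 1)

  chS <- chol(config$Sigma)
  b <- t(matrix(stats::rnorm(n * p), n, p) %*% chS) + config$beta
  lnsig2 <- stats::rnorm(n, config$mu, sqrt(config$tau2))

  early <- stats::runif(n) < config$early_frac
  nvis <- 3L + stats::rpois(n, config$visit_lambda)
  long <- vector("list", n)
  for (i in seq_len(n)) {
    upper <- min(config$visit_range[2L], subjects$ga_delivery_weeks[i])
    times <- sample_visit_times(if (early[i]) "early" else "late",
                                nvis[i], upper, config)
    wts <- evaluate_trajectory(times, b[, i], grid) +
      stats::rnorm(length(times), 0, sqrt(exp(lnsig2[i])))
    src <- rep("clinical", length(times))
    if (config$include_selfreport) {
      sr <- evaluate_trajectory(0, b[, i], grid) +
        config$selfreport_bias_mean +
        stats::rnorm(1, 0, config$selfreport_bias_sd)
      times <- c(0, times); wts <- c(sr, wts); src <- c("self_report", src)
    }
    long[[i]] <- data.frame(subject_id = subjects$subject_id[i],
                            ga_weeks = times, weight_kg = wts, source = src)
  }
  long <- do.call(rbind, long)

  Z <- stats::model.matrix(
    stats::reformulate(c(names(freq), "age_years", "ga_delivery_weeks")),
    data = subjects)[, -1L, drop = FALSE]
  tz <- rep(0, ncol(Z))
  names(tz) <- colnames(Z)
  hit <- intersect(names(config$theta_z), colnames(Z))
  tz[hit] <- config$theta_z[hit]
  eta <- config$theta0 + drop(Z %*% tz) + drop(crossprod(b, config$theta_b)) +
    config$theta_v * lnsig2
  subjects$birth_weight_kg <- eta + stats::rnorm(n, 0, sqrt(config$sigma2))

  effects <- data.frame(subject_id = subjects$subject_id, t(b),
                        lnsig2 = lnsig2, sigma_i2 = exp(lnsig2),
                        recruitment = ifelse(early, "early", "late"))
  names(effects)[1L + seq_len(p)] <- paste0("b", 0:grid$K)
  truth <- list(effects = effects,
                params = list(beta = config$beta, Sigma = config$Sigma,
                              mu = config$mu, tau2 = config$tau2,
                              theta0 = config$theta0, theta_z = tz,
                              theta_b = config$theta_b,
                              theta_v = config$theta_v,
                              sigma2 = config$sigma2,
                              knots = grid$knots))
  gwg_cohort(subjects, long, truth)
}

#' Apply cohort inclusion filters
#'
#' Drops subjects without a recorded pregravid (week-0) weight, with fewer
#' than three clinical weight measurements during pregnancy, or with a
#' missing covariate or outcome field, and reports the count excluded by
#' each rule (a subject is counted under every rule it violates).
#'
#' @param cohort A `gwg_cohort`.
#' @return List with the filtered `cohort` and an `exclusions` data frame
#'   (rule, n_excluded), plus kept/total counts.
#' @export
apply_inclusion_filters <- function(cohort) {
  stopifnot(inherits(cohort, "gwg_cohort"))
  subj <- cohort$subjects
  long <- cohort$long
  has_pregravid <- subj$subject_id %in%
    long$subject_id[long$source == "self_report" & long$ga_weeks == 0]
  ncl <- table(factor(long$subject_id[long$source == "clinical"],
                      levels = subj$subject_id))
  enough <- as.integer(ncl[subj$subject_id]) >= 3L
  complete <- stats::complete.cases(subj)
  keep <- has_pregravid & enough & complete
  exclusions <- data.frame(
    rule = c("missing_pregravid_weight", "fewer_than_3_measurements",
             "missing_covariate_or_outcome"),
    n_excluded = c(sum(!has_pregravid), sum(!enough), sum(!complete)))
  kept_ids <- subj$subject_id[keep]
  out <- gwg_cohort(subj[keep, , drop = FALSE],
                    long[long$subject_id %in% kept_ids, , drop = FALSE],
                    truth = if (!is.null(cohort$truth)) {
                      tr <- cohort$truth
                      tr$effects <- tr$effects[
                        tr$effects$subject_id %in% kept_ids, , drop = FALSE]
                      tr
                    })
  list(cohort = out, exclusions = exclusions,
       n_kept = sum(keep), n_total = nrow(subj))
}
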