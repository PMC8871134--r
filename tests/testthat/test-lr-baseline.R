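scheme <- interval_scheme()

test_that("the default interval scheme has the standard midpoints", {
  expect_equal(scheme$midpoints, c(6.5, 15.5, 20.5, 25, 29.5, 34.5, 41))
  expect_equal(scheme$K, 7L)
  expect_error(interval_scheme(c(5, 13)), "first boundary")
})

test_that("interval means average within half-open intervals", {
  d <- data.frame(ga_weeks = c(0, 14, 16), weight_kg = c(60, 60, 62))
  mu <- interval_means(d, scheme)
  expect_equal(unname(mu["mu0"]), 60)
  expect_equal(unname(mu["mu2"]), 61)
  expect_true(is.na(mu["mu3"]))
  # a measurement at exactly t = 13 belongs to [13,18), not [0,13)
  d2 <- data.frame(ga_weeks = c(13), weight_kg = c(70))
  mu2 <- interval_means(d2, scheme)
  expect_true(is.na(mu2["mu1"]))
  expect_equal(unname(mu2["mu2"]), 70)
})

test_that("rate features follow the midpoint difference formula", {
  mu <- c(60, 62.6, rep(NA, 6))
  names(mu) <- paste0("mu", 0:7)
  bt <- rate_features(mu, scheme)
  expect_equal(unname(bt["bt0"]), 60)
  expect_equal(unname(bt["bt1"]), (62.6 - 60) / 6.5)
  expect_true(is.na(bt["bt2"]))
  # equal adjacent means give rate zero
  mu2 <- c(60, 60, 60, rep(NA, 5))
  names(mu2) <- names(mu)
  expect_equal(unname(rate_features(mu2, scheme)["bt2"]), 0)
})

test_that("shifting all weights changes only the pregravid feature", {
  co <- simulate_cohort(synth_config(n = 20, seed = 20))
  f1 <- lr_features(co, scheme)
  co2 <- co
  co2$long$weight_kg <- co2$long$weight_kg + 5
  f2 <- lr_features(co2, scheme)
  expect_equal(f2$bt0, f1$bt0 + 5, tolerance = 1e-10)
  for (k in 1:7)
    expect_equal(f2[[paste0("bt", k)]], f1[[paste0("bt", k)]],
                 tolerance = 1e-10)
})

# cohort whose outcome is an exact linear rule of the LR features
linear_rule_cohort <- function(n, seed, noise_sd = 0) {
  co <- simulate_cohort(synth_config(n = n, seed = seed,
                                     visit_lambda = 25))
  f <- lr_features(co, scheme)
  keep <- stats::complete.cases(f)
  co$subjects <- co$subjects[keep, , drop = FALSE]
  co$long <- co$long[co$long$subject_id %in% co$subjects$subject_id, ]
  f <- f[keep, , drop = FALSE]
  truth <- c(1.5, 0.02, seq(0.1, 0.7, by = 0.1))
  X <- as.matrix(cbind(1, f[, paste0("bt", 0:7)]))
  set.seed(seed + 1)
  co$subjects$birth_weight_kg <- drop(X %*% truth) +
    0.1 * co$subjects$age_years +
    rnorm(nrow(X), 0, noise_sd)
  list(cohort = co, truth = truth)
}

test_that("noiseless linear outcomes are recovered exactly", {
  lrc <- linear_rule_cohort(60, seed = 21)
  # a perfect fit makes lm warn about unreliable summaries; that is the point
  fit <- suppressWarnings(fit_lr(lrc$cohort, scheme,
                                 covariates = "age_years"))
  cf <- fit$coef_table
  expect_equal(cf$estimate[cf$term == "(Intercept)"], 1.5, tolerance = 1e-8)
  expect_equal(cf$estimate[cf$term == "age_years"], 0.1, tolerance = 1e-8)
  expect_equal(cf$estimate[cf$term == "bt0"], 0.02, tolerance = 1e-8)
  expect_equal(cf$estimate[cf$term == "bt7"], 0.7, tolerance = 1e-8)
})

test_that("LR coefficients match the explicit normal-equations oracle", {
  lrc <- linear_rule_cohort(80, seed = 22, noise_sd = 0.3)
  fit <- fit_lr(lrc$cohort, scheme, covariates = "age_years")
  dat <- fit$data
  X <- as.matrix(cbind(1, dat$age_years, dat[, paste0("bt", 0:7)]))
  coef_or <- drop(MASS::ginv(X) %*% dat$birth_weight_kg)
  expect_equal(unname(fit$coef_table$estimate), coef_or, tolerance = 1e-10)
  expect_equal(fit$n_used, nrow(dat))
})

test_that("confidence intervals are calibrated across replicates", {
  covered <- matrix(NA, 100, 10)
  for (r in 1:100) {
    lrc <- linear_rule_cohort(150, seed = 3000 + r, noise_sd = 0.3)
    fit <- fit_lr(lrc$cohort, scheme, covariates = "age_years")
    cf <- fit$coef_table
    truth_all <- c(lrc$truth[1], 0.1, lrc$truth[-1])
    ord <- c("(Intercept)", "age_years", paste0("bt", 0:7))
    cf <- cf[match(ord, cf$term), ]
    covered[r, ] <- cf$lower <= truth_all & truth_all <= cf$upper
  }
  rate <- mean(covered)
  expect_gte(rate, 0.90)
  expect_lte(rate, 0.99)
})

test_that("pruning keeps significant demographics and all rate features", {
  set.seed(23)
  co <- simulate_cohort(synth_config(n = 800, seed = 23, visit_lambda = 25,
                                     theta_z = c("parity1" = 0.5,
                                                 "parity2+" = 0.8,
                                                 "ga_delivery_weeks" = 0.162)))
  fit <- fit_lr(co, scheme)
  red <- prune_and_refit(fit)
  kept <- attr(red, "kept_covariates")
  expect_true(all(c("parity", "ga_delivery_weeks") %in% kept))
  # null-effect covariates with CIs containing zero are dropped
  tm <- gwjoint:::assign_terms(fit$covariates, fit$data)
  cf <- fit$coef_table
  for (cv in setdiff(fit$covariates, kept)) {
    cols <- names(tm)[tm == cv]
    rows <- cf[cf$term %in% cols, ]
    expect_true(all(rows$lower <= 0 & rows$upper >= 0))
  }
  # rate features are always retained
  expect_true(all(paste0("bt", 0:7) %in% red$coef_table$term))
})
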