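grid <- changepoint_grid()

# tiny hand-built cohort: 2 subjects, simple trajectories
toy_cohort <- function() {
  subjects <- data.frame(subject_id = c("A", "B"),
                         age_years = c(30, 32),
                         ga_delivery_weeks = c(39, 40),
                         birth_weight_kg = c(3.2, 3.6))
  long <- data.frame(
    subject_id = c("A", "A", "A", "A", "B", "B", "B"),
    ga_weeks = c(0, 10, 20, 35, 0, 15, 30),
    weight_kg = c(60, 63, 68, 75, 70, 75, 82),
    source = c("self_report", rep("clinical", 3),
               "self_report", rep("clinical", 2)))
  gwg_cohort(subjects, long)
}

test_that("linear predictor is the inner product of the stacked design row", {
  theta <- c(1.5, rep(0, 2), rep(0, 9), 0)
  expect_equal(linear_predictor(theta, c(0, 0), rep(0, 9), 0), 1.5)
  expect_equal(linear_predictor(rep(0, 13), c(1, 2), rnorm(9), 3), 0)
  # theta_0 = 1, theta_v = 2, sigma_i^2 = e^2: 1 + 2 * 2 = 5
  theta <- c(1, rep(0, 11), 2)
  expect_equal(linear_predictor(theta, c(0, 0), rep(0, 9), log(exp(2))), 5)
  expect_error(linear_predictor(rep(0, 5), c(0, 0), rep(0, 9), 0), "length")
})

test_that("linear predictor is linear in theta", {
  set.seed(6)
  z <- rnorm(3); b <- rnorm(9); l <- 0.4
  t1 <- rnorm(14); t2 <- rnorm(14)
  expect_equal(linear_predictor(3 * t1 - t2, z, b, l),
               3 * linear_predictor(t1, z, b, l) -
                 linear_predictor(t2, z, b, l))
})

test_that("log joint matches a hand-computed single-subject value", {
  g1 <- changepoint_grid(c(0))  # basis (1, t)
  subjects <- data.frame(subject_id = "A", birth_weight_kg = 3,
                         ga_delivery_weeks = 39)
  long <- data.frame(subject_id = "A", ga_weeks = 10, weight_kg = 62,
                     source = "clinical")
  co <- gwg_cohort(subjects, long)
  md <- prepare_model_data(co, g1, covariates = NULL)
  pr <- prior_spec(g1, Lambda = diag(2), sigma_prior = "invwishart",
                   wishart_df = 4)
  # state with zero residuals everywhere and unit variances
  b <- matrix(c(62 - 10, 1), 2, 1)     # passes through (10, 62) with slope 1
  theta <- c(3, 0, 0, 0)               # intercept reproduces Y exactly
  st <- param_state(theta = theta, sigma2 = 1, beta = b[, 1],
                    Sigma = diag(2), mu = 0, tau2 = 1, b = b, lnsig2 = 0)
  # by hand: every Gaussian term sits at its mode, so the log density is a
  # sum of log-normalizers: three univariate and one bivariate standard
  # normal
  lhand <- 3 * dnorm(0, log = TRUE) - log(2 * pi)
  lprior <- sum(dnorm(theta, 0, sqrt(10), log = TRUE)) +
    sum(dnorm(b[, 1], 0, sqrt(10), log = TRUE)) +
    gwjoint:::ldinvgamma(1, 1e-4, 1e-4) * 2 +         # sigma2 and tau2
    dnorm(0, 0, sqrt(1e3), log = TRUE) +
    gwjoint:::ldinvwishart(diag(2), 4, diag(2))
  expect_equal(log_joint(st, md, pr), lhand + lprior, tolerance = 1e-10)
})

test_that("log joint is invariant to subject order and decomposes by subject", {
  co <- toy_cohort()
  md <- prepare_model_data(co, grid, covariates = "age_years")
  pr <- prior_spec(grid)
  st <- init_state(md)
  lp <- log_joint(st, md, pr)
  # reorder subjects
  co2 <- gwg_cohort(co$subjects[2:1, ], co$long)
  md2 <- prepare_model_data(co2, grid, covariates = "age_years")
  st2 <- st
  st2$b <- st$b[, 2:1]
  st2$lnsig2 <- st$lnsig2[2:1]
  expect_equal(log_joint(st2, md2, pr), lp, tolerance = 1e-10)
  # perturbing one subject's data changes only that subject's summands:
  # recompute the same change from a single-subject cohort
  co3 <- co
  co3$long$weight_kg[2] <- co3$long$weight_kg[2] + 1
  md3 <- prepare_model_data(co3, grid, covariates = "age_years")
  delta_full <- log_joint(st, md3, pr) - lp
  one <- function(long) {
    c1 <- gwg_cohort(co$subjects[1, , drop = FALSE], long)
    m1 <- prepare_model_data(c1, grid, covariates = "age_years")
    s1 <- st; s1$b <- st$b[, 1, drop = FALSE]; s1$lnsig2 <- st$lnsig2[1]
    log_joint(s1, m1, pr)
  }
  la <- one(co$long[co$long$subject_id == "A", ])
  lb <- one(co3$long[co3$long$subject_id == "A", ])
  expect_equal(delta_full, lb - la, tolerance = 1e-10)
})

test_that("log joint decreases when a longitudinal residual grows", {
  co <- toy_cohort()
  md <- prepare_model_data(co, grid, covariates = "age_years")
  pr <- prior_spec(grid)
  st <- init_state(md)
  lp0 <- log_joint(st, md, pr)
  co2 <- co
  fit_at <- evaluate_trajectory(co$long$ga_weeks[3], st$b[, 1], grid)
  co2$long$weight_kg[3] <- fit_at +
    2 * abs(co$long$weight_kg[3] - fit_at) + 1
  md2 <- prepare_model_data(co2, grid, covariates = "age_years")
  expect_lt(log_joint(st, md2, pr), lp0)
  # non-PD Sigma errors
  st_bad <- st
  st_bad$Sigma <- matrix(-1, 9, 9)
  expect_error(log_joint(st_bad, md, pr), "positive definite")
})

test_that("empirical-Bayes Wishart scale follows the sum-of-inverses parse", {
  fake_fit <- function(covm) {
    structure(list(coef = rep(0, 9), cov = covm, sigma2 = 1,
                   identifiable = rep(TRUE, 9), rank_ok = TRUE, n = 20),
              class = "subject_ols")
  }
  pr1 <- empirical_bayes_wishart(list(fake_fit(diag(9))), grid)
  expect_equal(pr1$Lambda, diag(9))
  pr2 <- empirical_bayes_wishart(list(fake_fit(2 * diag(9)),
                                      fake_fit(2 * diag(9))), grid)
  expect_equal(pr2$Lambda, diag(9))
  # default degrees of freedom for the standard grid: K + 3 = 11
  expect_equal(pr2$wishart_df, 11)
  # normalization switch divides by the subject count
  pr3 <- empirical_bayes_wishart(list(fake_fit(diag(9)), fake_fit(diag(9))),
                                 grid, normalize = TRUE)
  expect_equal(pr3$Lambda, diag(9))
  # inverse-of-sum parse
  pr4 <- empirical_bayes_wishart(list(fake_fit(diag(9)), fake_fit(diag(9))),
                                 grid, parse = "inverse_of_sum")
  expect_equal(pr4$Lambda, 0.5 * diag(9))
  expect_error(empirical_bayes_wishart(list(), grid), "supply Lambda")
})

test_that("prior spec validates its hyperparameters", {
  expect_error(prior_spec(grid, wishart_df = 5), "proper")
  expect_error(prior_spec(grid, Lambda = diag(3)), "9 x 9")
  expect_error(prior_spec(grid, theta_var = -1), "positive")
})
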