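test_that("PSRF matches hand arithmetic on a 2-chain x 3-draw toy", {
  chains <- list(c(1, 2, 3), c(2, 3, 7))
  n <- 3
  means <- c(2, 4)
  W <- mean(c(var(c(1, 2, 3)), var(c(2, 3, 7))))  # (1 + 7)/2 = 4
  B <- n * var(means)                             # 3 * 2 = 6
  V <- (n - 1) / n * W + B / n
  expect_equal(gelman_rubin(chains), sqrt(V / W), tolerance = 1e-12)
  expect_error(gelman_rubin(list(c(1, 2))), "two chains")
  expect_error(gelman_rubin(list(1:3, 1:4)), "equal retained lengths")
})

test_that("PSRF is near 1 for identically distributed chains and large for separated ones", {
  set.seed(30)
  same <- replicate(4, rnorm(10000), simplify = FALSE)
  expect_lt(gelman_rubin(same), 1.05)
  expect_gt(gelman_rubin(same), 0.99)
  apart <- list(rnorm(10000, 0, 1e-3), rnorm(10000, 100, 1e-3))
  expect_gt(gelman_rubin(apart), 1.2)
})

test_that("credible intervals follow the linear-interpolation quantile convention", {
  expect_equal(credible_interval(rep(3.2, 10)), c(3.2, 3.2))
  draws <- as.numeric(1:1000)
  expect_equal(credible_interval(draws, 0.95),
               unname(quantile(draws, c(0.025, 0.975), type = 7)))
  # widening the level never narrows the interval
  set.seed(31)
  x <- rnorm(500)
  ci80 <- credible_interval(x, 0.80)
  ci95 <- credible_interval(x, 0.95)
  expect_lte(ci95[1], ci80[1])
  expect_gte(ci95[2], ci80[2])
  expect_error(credible_interval(1), "at least two")
})

test_that("cumulative rate effects are running sums of the slope effects", {
  g <- changepoint_grid()
  th <- matrix(0, 1, 9 + 2)
  colnames(th) <- c("(Intercept)", paste0("b", 0:8), "ln_sigma_i2")
  th[1, paste0("b", 1:8)] <- c(0.7, 0.5, 0.4, 0.2, 0.1, 0, 0, 0.1)
  eff <- cumulative_rate_effects(rbind(th, th), grid = g)
  expect_equal(unname(eff$draws[1, ]),
               c(0.7, 1.2, 1.6, 1.8, 1.9, 1.9, 1.9))
  expect_equal(colnames(eff$draws)[1], "[0,13)")
  # terminal slope change excluded
  expect_equal(ncol(eff$draws), 7L)
  # k = 1 effect equals theta_b1 draw for draw
  set.seed(32)
  thr <- matrix(rnorm(20 * 11), 20, 11,
                dimnames = list(NULL, colnames(th)))
  effr <- cumulative_rate_effects(thr, grid = g)
  expect_equal(unname(effr$draws[, 1]), unname(thr[, "b1"]))
  # all-positive slope effects give nondecreasing cumulative effects
  thp <- abs(thr)
  effp <- cumulative_rate_effects(thp, grid = g)
  expect_true(all(diff(t(effp$draws)) >= 0))
  # difference mode gives the single-interval marginal effect
  effd <- cumulative_rate_effects(thr, grid = g, mode = "difference")
  expect_equal(unname(effd$draws[, 2]),
               unname(thr[, "b2"] - thr[, "b3"]))
})

test_that("summary tables order rows and flag intervals excluding zero", {
  co <- simulate_cohort(synth_config(n = 40, seed = 33))
  fit <- fit_jm(co, covariates = c("parity", "ga_delivery_weeks"),
                config = mcmc_config(iterations = 600, burnin = 300,
                                     thin = 3, chains = 1, seed = 2,
                                     grid_size = 128))
  tab <- summary_table(fit)
  expect_equal(tab$parameter[1:3],
               c("parity1", "parity2+", "ga_delivery_weeks"))
  expect_equal(tab$parameter[4], "pregravid_weight (b0)")
  expect_match(tab$parameter[5], "residual_variance")
  expect_equal(tab$parameter[6:12], paste("rate",
               c("[0,13)", "[13,18)", "[18,23)", "[23,27)", "[27,32)",
                 "[32,37)", "[37,45)")))
  expect_equal(tab$excludes_zero, tab$lower > 0 | tab$upper < 0)
  expect_true(all(tab$lower <= tab$upper))
  # flag logic on known intervals
  expect_true((function(l, u) l > 0 | u < 0)(0.02, 0.27))
  expect_false((function(l, u) l > 0 | u < 0)(-0.16, 0.47))
  # LR variant shares the layout (denser visits so complete cases remain);
  # locate rows by label since lm drops factor levels unused after
  # complete-case filtering
  cod <- simulate_cohort(synth_config(n = 60, seed = 35, visit_lambda = 25))
  lrt <- summary_table(fit_lr(cod, covariates = c("parity",
                                                  "ga_delivery_weeks")))
  ip <- grep("pregravid", lrt$parameter)
  expect_length(ip, 1L)
  expect_equal(lrt$parameter[ip + 1], "rate [0,13)")
  expect_true(all(grepl("^rate ", lrt$parameter[(ip + 1):nrow(lrt)])))
})

test_that("trajectory plots write files and the mean curve matches the basis", {
  co <- simulate_cohort(synth_config(n = 30, seed = 34))
  fit <- fit_jm(co, covariates = NULL,
                config = mcmc_config(iterations = 400, burnin = 200,
                                     thin = 2, chains = 1, seed = 3,
                                     grid_size = 128),
                save_b_idx = c(1L, 2L))
  td <- withr::local_tempdir()
  f <- file.path(td, "traj.png")
  res <- plot_trajectories(fit, subjects = 1:2, file = f)
  expect_true(file.exists(f) && file.size(f) > 0)
  expect_true(all(res$band[2, ] >= res$band[1, ]))
  # population curve is the basis evaluated at the posterior mean of beta
  bbar <- colMeans(pooled_draws(fit, "beta"))
  expect_equal(res$mean, drop(basis_row(res$t, changepoint_grid()) %*% bbar),
               tolerance = 1e-10)
})

test_that("JM pruning reuses the LR keep/drop rule on identical intervals", {
  # identical interval inputs must give identical keep/drop decisions
  dat <- data.frame(parity = factor(c("0", "1", "2+"),
                                    levels = c("0", "1", "2+")),
                    age_years = c(30, 31, 32))
  tm <- gwjoint:::assign_terms(c("parity", "age_years"), dat)
  lower <- c(0.02, -0.1, -0.2)
  upper <- c(0.30, 0.05, 0.1)
  names(lower) <- names(upper) <- names(tm)
  kept <- gwjoint:::kept_demographics(c("parity", "age_years"), dat, tm,
                                      lower, upper)
  expect_equal(kept, "parity")  # one level excludes zero -> variable kept
})
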