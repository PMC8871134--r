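test_that("noise-free self-report reproduces the trajectory intercept", {
  co <- simulate_cohort(synth_config(n = 30, seed = 10,
                                     selfreport_bias_mean = 0,
                                     selfreport_bias_sd = 0))
  sr <- co$long[co$long$source == "self_report", ]
  b0 <- co$truth$effects$b0[match(sr$subject_id, co$truth$effects$subject_id)]
  expect_equal(sr$weight_kg, b0, tolerance = 1e-12)
  expect_true(all(sr$ga_weeks == 0))
})

test_that("a constant bias shifts every self-report by that amount", {
  co <- simulate_cohort(synth_config(n = 30, seed = 10,
                                     selfreport_bias_mean = 2,
                                     selfreport_bias_sd = 0))
  sr <- co$long[co$long$source == "self_report", ]
  b0 <- co$truth$effects$b0[match(sr$subject_id, co$truth$effects$subject_id)]
  expect_equal(sr$weight_kg, b0 + 2, tolerance = 1e-12)
})

test_that("tau2 = 0 makes every residual variance equal exp(mu)", {
  co <- simulate_cohort(synth_config(n = 15, seed = 11, tau2 = 0,
                                     mu = log(0.81)))
  expect_equal(co$truth$effects$sigma_i2, rep(0.81, 15), tolerance = 1e-12)
})

test_that("sampled random effects average to beta (law of large numbers)", {
  cfg <- synth_config(n = 10000, seed = 12)
  co <- simulate_cohort(cfg)
  b <- as.matrix(co$truth$effects[, paste0("b", 0:8)])
  se <- sqrt(diag(cfg$Sigma) / nrow(b))
  expect_true(all(abs(colMeans(b) - cfg$beta) < 4 * se + 1e-12))
})

test_that("visit times respect recruitment class constraints", {
  cfg <- synth_config(seed = NULL)
  set.seed(13)
  for (r in 1:200) {
    late <- sample_visit_times("late", n_visits = 5, upper = 41, cfg)
    expect_true(min(late) >= 14)
    expect_true(max(late) <= 41.7)
    early <- sample_visit_times("early", n_visits = 3 + rpois(1, 9),
                                upper = 40, cfg)
    expect_true(any(early < 13))          # first trimester
    expect_true(any(early >= 14 & early <= 27))  # second
    expect_true(any(early >= 28))         # third
    expect_false(is.unsorted(early))
  }
})

test_that("visit counts hit the configured median", {
  set.seed(14)
  counts <- 3 + rpois(10000, synth_config(seed = NULL)$visit_lambda)
  expect_lte(abs(median(counts) - 12), 1)
  # and the generator's clinical visit counts match (delivery capping does
  # not drop visits, it compresses their range)
  co <- simulate_cohort(synth_config(n = 2000, seed = 15))
  ncl <- table(co$long$subject_id[co$long$source == "clinical"])
  expect_lte(abs(median(ncl) - 12), 1)
  expect_true(all(ncl >= 3))
})

test_that("inclusion filters drop exactly the rule-violating subjects", {
  co <- simulate_cohort(synth_config(n = 5, seed = 16))
  # subject 1: strip the pregravid row; subject 2: leave 2 clinical obs;
  # subject 3: missing outcome; subjects 4-5 intact
  ids <- co$subjects$subject_id
  long <- co$long
  long <- long[!(long$subject_id == ids[1] & long$source == "self_report"), ]
  cl2 <- which(long$subject_id == ids[2] & long$source == "clinical")
  long <- long[-cl2[-(1:2)], ]
  subj <- co$subjects
  subj$birth_weight_kg[3] <- NA
  res <- apply_inclusion_filters(gwg_cohort(subj, long))
  expect_equal(res$n_kept, 2L)
  expect_equal(res$cohort$subjects$subject_id, ids[4:5])
  ex <- res$exclusions
  expect_equal(ex$n_excluded[ex$rule == "missing_pregravid_weight"], 1L)
  expect_equal(ex$n_excluded[ex$rule == "fewer_than_3_measurements"], 1L)
  expect_equal(ex$n_excluded[ex$rule == "missing_covariate_or_outcome"], 1L)
  # boundary: exactly 3 clinical measurements is kept
  res2 <- apply_inclusion_filters(co)
  expect_equal(res2$n_kept, 5L)
  expect_true(all(res2$exclusions$n_excluded == 0L))
})

test_that("dense noise-free sampling lets subject OLS recover each b_i", {
  cfg <- synth_config(n = 5, seed = 17, mu = log(1e-8), tau2 = 0,
                      visit_lambda = 120)
  co <- simulate_cohort(cfg)
  g <- changepoint_grid()
  for (i in 1:5) {
    id <- co$subjects$subject_id[i]
    d <- co$long[co$long$subject_id == id, ]
    fit <- subject_ols(d$ga_weeks, d$weight_kg, g)
    idx <- which(fit$identifiable)
    truth <- as.numeric(co$truth$effects[i, paste0("b", 0:8)])
    expect_equal(fit$coef[idx], truth[idx], tolerance = 1e-3)
  }
})

test_that("the truth ledger round-trips through CSV unchanged", {
  co <- simulate_cohort(synth_config(n = 8, seed = 18))
  td <- withr::local_tempdir()
  write_cohort(co, file.path(td, "s.csv"), file.path(td, "l.csv"),
               file.path(td, "t.csv"))
  back <- read_cohort(file.path(td, "s.csv"), file.path(td, "l.csv"),
                      file.path(td, "t.csv"))
  expect_equal(back$truth$effects$b0, co$truth$effects$b0, tolerance = 1e-12)
  expect_equal(back$truth$effects$lnsig2, co$truth$effects$lnsig2,
               tolerance = 1e-12)
})
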