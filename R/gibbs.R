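#' MCMC configuration
#'
#' Defaults follow the headline settings: 150,000 iterations with the first
#' 50,000 as burn-in, thinning to every 10th draw, and five chains. The
#' fast preset (10,000 total iterations) is adequate for this model, which
#' mixes quickly; it keeps the same thinning and burns the first half.
#'
#' @param iterations Total iterations per chain.
#' @param burnin Burn-in iterations discarded from the front.
#' @param thin Retain every `thin`-th post-burn-in draw.
#' @param chains Number of independent chains.
#' @param seed Base RNG seed; chain `c` uses `seed + c - 1`.
#' @param grid_size Number of grid points for the inverse-CDF draw of
#'   `ln sigma_i^2` (>= 64).
#' @param span_mult,span_min The grid spans the conditional mode plus/minus
#'   `max(span_mult * tau, span_min)` on the log scale.
#' @param fast Logical; if `TRUE` apply the fast preset
#'   (iterations = 10000, burnin = 5000).
#' @return An object of class `mcmc_config`.
#' @export
mcmc_config <- function(iterations = 150000, burnin = 50000, thin = 10,
                        chains = 5, seed = 1, grid_size = 2048,
                        span_mult = 8, span_min = 10, fast = FALSE) {
  if (fast) {
    iterations <- 10000
    burnin <- 5000
  }
  if (burnin >= iterations) stop("burnin must be smaller than iterations")
  if (thin < 1) stop("thin must be >= 1")
  if (grid_size < 64) stop("grid_size must be >= 64")
  if (chains < 1) stop("at least one chain required")
  structure(list(iterations = as.integer(iterations),
                 burnin = as.integer(burnin), thin = as.integer(thin),
                 chains = as.integer(chains), seed = as.integer(seed),
                 grid_size = as.integer(grid_size),
                 span_mult = span_mult, span_min = span_min),
            class = "mcmc_config")
}

theta_split <- function(theta, q, p) {
  d <- length(theta)
  list(theta0 = theta[1L],
       theta_z = if (q > 0) theta[1L + seq_len(q)] else numeric(0),
       theta_b = theta[1L + q + seq_len(p)],
       theta_v = theta[d])
}

unvech <- function(v, p) {
  M <- matrix(0, p, p)
  M[lower.tri(M, diag = TRUE)] <- v
  M + t(M) - diag(diag(M))
}

priors_cpp <- function(priors) {
  list(theta_var = priors$theta_var, beta_var = priors$beta_var,
       sigma2_shape = priors$sigma2_shape, sigma2_rate = priors$sigma2_rate,
       tau2_shape = priors$tau2_shape, tau2_rate = priors$tau2_rate,
       mu_mean = priors$mu_mean, mu_var = priors$mu_var,
       wishart_df = priors$wishart_df, Lambda = priors$Lambda,
       sigma_mode = if (priors$sigma_prior == "invwishart") 1L else 0L)
}

#' Gibbs update of all subject trajectory coefficients
#'
#' Draws each `b_i` from its exact Gaussian full conditional, which
#' combines the longitudinal likelihood, the `N(beta, Sigma)` prior, and
#' the outcome term through which `b_i` predicts birth weight.
#'
#' @param state A [param_state()].
#' @param mdata A [prepare_model_data()] object.
#' @param priors A [prior_spec()].
#' @return The state with updated `b`.
#' @export
draw_random_effects <- function(state, mdata, priors) {
  ts <- theta_split(state$theta, mdata$q, mdata$p)
  for (i in seq_len(mdata$n)) {
    ry <- mdata$Y[i] - ts$theta0 -
      (if (mdata$q > 0) sum(mdata$Z[i, ] * ts$theta_z) else 0) -
      ts$theta_v * state$lnsig2[i]
    state$b[, i] <- drop(gwg_draw_b_rep(mdata$G[, , i], mdata$h[, i],
                                        state$lnsig2[i], state$Sigma,
                                        state$beta, ts$theta_b, ry,
                                        state$sigma2, 1L))
  }
  state
}

subject_ssr_ay <- function(state, mdata, i) {
  ts <- theta_split(state$theta, mdata$q, mdata$p)
  bi <- state$b[, i]
  ssr <- max(0, mdata$xx[i] - 2 * sum(bi * mdata$h[, i]) +
               drop(crossprod(bi, mdata$G[, , i] %*% bi)))
  ay <- ts$theta0 +
    (if (mdata$q > 0) sum(mdata$Z[i, ] * ts$theta_z) else 0) +
    sum(ts$theta_b * bi)
  list(ssr = ssr, ay = ay, theta_v = ts$theta_v)
}

#' Gibbs update of all subject residual variances
#'
#' The full conditional of `ln sigma_i^2` has no closed form; it is drawn
#' by evaluating the unnormalized log conditional on a log-scale grid
#' centered at the conditional mode and inverting the discrete CDF with
#' within-cell linear interpolation.
#'
#' @inheritParams draw_random_effects
#' @param config An [mcmc_config()] (grid settings).
#' @return The state with updated `lnsig2`.
#' @export
draw_sigma_i2 <- function(state, mdata, priors, config = mcmc_config()) {
  for (i in seq_len(mdata$n)) {
    sa <- subject_ssr_ay(state, mdata, i)
    state$lnsig2[i] <- gwg_draw_lnsig2_rep(
      mdata$nobs[i], sa$ssr, state$mu, state$tau2, sa$theta_v, sa$ay,
      mdata$Y[i], state$sigma2, config$grid_size, config$span_mult,
      config$span_min, state$lnsig2[i], 1L)
  }
  state
}

#' Gibbs update of the mean trajectory
#'
#' Exact Gaussian conditional combining the `N(0, beta_var I)` prior with
#' the sample of subject coefficients.
#' @inheritParams draw_random_effects
#' @return The state with updated `beta`.
#' @export
draw_beta <- function(state, priors) {
  mom <- gwg_cond_beta(state$b, state$Sigma, priors$beta_var)
  state$beta <- drop(mom$mean) +
    drop(t(chol(mom$cov)) %*% stats::rnorm(length(mom$mean)))
  state
}

#' Gibbs update of the random-effect covariance
#'
#' In the default Wishart-on-covariance mode the non-conjugate conditional
#' is advanced by one Metropolis-within-Gibbs step with an inverse-Wishart
#' independence proposal fitted to the scatter of the `b_i` about `beta`.
#' In the conjugate `"invwishart"` mode the exact inverse-Wishart
#' conditional is drawn.
#' @inheritParams draw_random_effects
#' @return The state with updated `Sigma`; the attribute `"accepted"`
#'   reports the MH acceptance (always `TRUE` in conjugate mode).
#' @export
draw_Sigma <- function(state, priors) {
  p <- nrow(state$b)
  D <- state$b - state$beta
  S <- tcrossprod(D)
  n <- ncol(state$b)
  if (priors$sigma_prior == "invwishart") {
    pars <- gwg_sigma_conj_params(S, n, priors$wishart_df, priors$Lambda)
    v <- gwg_draw_invwishart_rep(pars$df, pars$scale, 1L)
    state$Sigma <- unvech(drop(v), p)
    attr(state, "accepted") <- TRUE
  } else {
    res <- gwg_sigma_mh_chain(state$Sigma, S, n, priors$wishart_df,
                              priors$Lambda, 1L)
    state$Sigma <- res$last
    attr(state, "accepted") <- res$accept > 0
  }
  state
}

#' Gibbs update of the outcome coefficients and residual variance
#'
#' `theta` is drawn from its exact ridge-like Gaussian conditional (prior
#' precision `1/theta_var`); `sigma2` from
#' Inv-Gamma(shape + n/2, rate + SSR/2).
#' @inheritParams draw_random_effects
#' @return The state with updated `theta` and `sigma2`.
#' @export
draw_outcome_params <- function(state, mdata, priors) {
  W <- cbind(1, mdata$Z, t(state$b), state$lnsig2)
  mom <- gwg_cond_theta(W, mdata$Y, state$sigma2, priors$theta_var)
  state$theta <- drop(mom$mean) +
    drop(t(chol(mom$cov)) %*% stats::rnorm(length(mom$mean)))
  res <- mdata$Y - drop(W %*% state$theta)
  state$sigma2 <- 1 / stats::rgamma(1, priors$sigma2_shape + mdata$n / 2,
                                    rate = priors$sigma2_rate + sum(res^2) / 2)
  state
}

#' Gibbs update of the residual-variance hyperparameters
#'
#' Normal-normal conditional for `mu` given the `ln sigma_i^2`, and
#' Inv-Gamma(shape + n/2, rate + sum((ln sigma_i^2 - mu)^2)/2) for `tau2`.
#' @inheritParams draw_random_effects
#' @return The state with updated `mu` and `tau2`.
#' @export
draw_variance_hyperparams <- function(state, priors) {
  n <- length(state$lnsig2)
  mom <- gwg_cond_mu(state$lnsig2, state$tau2, priors$mu_mean, priors$mu_var)
  state$mu <- stats::rnorm(1, mom$mean, sqrt(mom$var))
  ss <- sum((state$lnsig2 - state$mu)^2)
  state$tau2 <- 1 / stats::rgamma(1, priors$tau2_shape + n / 2,
                                  rate = priors$tau2_rate + ss / 2)
  state
}

#' Run one Gibbs chain
#'
#' Systematic-scan Gibbs sampler over the blocks (all `b_i`) -> (all
#' `sigma_i^2`) -> `beta` -> `Sigma` -> (`mu`, `tau2`) -> (`theta`,
#' `sigma2`), retaining every `thin`-th post-burn-in state. Identical
#' seeds give bit-identical draws.
#'
#' @param mdata A [prepare_model_data()] object.
#' @param priors A [prior_spec()].
#' @param config An [mcmc_config()].
#' @param seed Integer seed for this chain (default `config$seed`).
#' @param init Optional [param_state()] start; default [init_state()].
#' @param save_b_idx Subject indices whose `b_i` and `ln sigma_i^2` draws
#'   are retained in full (posterior means are always kept for everyone).
#' @return An object of class `jm_chain` with named draw matrices `theta`,
#'   `beta`, `Sigma` (half-vectorized), vectors `mu`, `tau2`, `sigma2`,
#'   selected-subject draws, per-subject posterior means, and metadata.
#' @export
run_chain <- function(mdata, priors, config = mcmc_config(),
                      seed = config$seed, init = NULL,
                      save_b_idx = integer(0)) {
  stopifnot(inherits(mdata, "jm_data"), inherits(priors, "prior_spec"),
            inherits(config, "mcmc_config"))
  if (is.null(init)) init <- init_state(mdata)
  set.seed(as.integer(seed))
  res <- gwg_gibbs_run(
    data = list(G = mdata$G, h = mdata$h, xx = mdata$xx,
                nobs = as.numeric(mdata$nobs), Z = mdata$Z, Y = mdata$Y),
    priors = priors_cpp(priors),
    init = init[c("theta", "sigma2", "beta", "Sigma", "mu", "tau2",
                  "b", "lnsig2")],
    config = list(iterations = config$iterations, burnin = config$burnin,
                  thin = config$thin, grid_size = config$grid_size,
                  span_mult = config$span_mult, span_min = config$span_min,
                  save_b_idx = as.integer(save_b_idx)))
  colnames(res$theta) <- mdata$theta_names
  bnames <- paste0("b", 0:mdata$grid$K)
  colnames(res$beta) <- bnames
  p <- mdata$p
  vn <- outer(seq_len(p), seq_len(p), function(i, j)
    paste0("Sigma[", i, ",", j, "]"))
  colnames(res$Sigma) <- vn[lower.tri(vn, diag = TRUE)]
  res$seed <- as.integer(seed)
  res$config <- config
  res$save_b_idx <- as.integer(save_b_idx)
  res$theta_names <- mdata$theta_names
  class(res) <- "jm_chain"
  res
}

#' Run multiple independent chains
#'
#' Chain `c` is seeded with `config$seed + c - 1` and initialized
#' identically (OLS-based start); chains are kept separate for
#' diagnostics. Because each chain's randomness is fully determined by its
#' own seed, results do not depend on execution order.
#'
#' @inheritParams run_chain
#' @return An object of class `jm_draws`: list of `jm_chain`s plus shared
#'   metadata.
#' @export
run_chains <- function(mdata, priors, config = mcmc_config(),
                       init = NULL, save_b_idx = integer(0)) {
  if (is.null(init)) init <- init_state(mdata)
  seeds <- config$seed + seq_len(config$chains) - 1L
  chains <- lapply(seeds, function(s)
    run_chain(mdata, priors, config, seed = s, init = init,
              save_b_idx = save_b_idx))
  structure(list(chains = chains, seeds = seeds, config = config,
                 theta_names = mdata$theta_names, grid = mdata$grid,
                 ids = mdata$ids),
            class = "jm_draws")
}

#' Fit the joint model to a cohort
#'
#' High-level wrapper: prepares the model data, builds the empirical-Bayes
#' Wishart prior from per-subject OLS fits (unless `priors` is supplied),
#' initializes from OLS, and runs the configured chains.
#'
#' @param cohort A `gwg_cohort`.
#' @param grid A [changepoint_grid()].
#' @param covariates Outcome demographic covariates (default
#'   [jm_covariates()]).
#' @param priors Optional [prior_spec()]; default empirical-Bayes Wishart.
#' @param config An [mcmc_config()].
#' @param include_self_report Include the week-0 self-report as a
#'   longitudinal observation (default `TRUE`).
#' @param save_b_idx Subjects whose trajectory draws are retained in full.
#' @param ... When `priors` is `NULL`, further arguments for
#'   [empirical_bayes_wishart()] / [prior_spec()] (e.g. `beta_var` for data
#'   kept in original units, where a kg-scale intercept needs a wider
#'   diffuse prior than the unit-scale default).
#' @return An object of class `jm_fit` containing the draws (`jm_draws`),
#'   the prepared data, and the prior specification.
#' @export
fit_jm <- function(cohort, grid = changepoint_grid(),
                   covariates = jm_covariates(), priors = NULL,
                   config = mcmc_config(), include_self_report = TRUE,
                   save_b_idx = integer(0), ...) {
  mdata <- prepare_model_data(cohort, grid, covariates, include_self_report)
  if (is.null(priors)) {
    fits <- lapply(seq_len(mdata$n), function(i)
      tryCatch(subject_ols(mdata$times[[i]], mdata$weights[[i]], grid),
               error = function(e) NULL))
    priors <- empirical_bayes_wishart(Filter(Negate(is.null), fits), grid,
                                      ...)
  }
  draws <- run_chains(mdata, priors, config, save_b_idx = save_b_idx)
  structure(list(draws = draws, mdata = mdata, priors = priors,
                 covariates = covariates),
            class = "jm_fit")
}

#' Pool a parameter's draws across chains
#'
#' @param draws A `jm_draws` or `jm_fit`.
#' @param component One of `"theta"`, `"beta"`, `"Sigma"`, `"mu"`,
#'   `"tau2"`, `"sigma2"`.
#' @return A matrix (draws x parameters) with chains stacked row-wise.
#' @export
pooled_draws <- function(draws, component = "theta") {
  if (inherits(draws, "jm_fit")) draws <- draws$draws
  stopifnot(inherits(draws, "jm_draws"))
  parts <- lapply(draws$chains, function(ch) {
    x <- ch[[component]]
    if (is.null(dim(x))) matrix(x, ncol = 1L, dimnames = list(NULL, component))
    else x
  })
  do.call(rbind, parts)
}

#' @export
print.jm_fit <- function(x, ...) {
  cfg <- x$draws$config
  cat("Joint model fit:", x$mdata$n, "subjects,",
      sum(x$mdata$nobs), "longitudinal observations\n")
  cat("Chains:", cfg$chains, "| iterations:", cfg$iterations,
      "| burn-in:", cfg$burnin, "| thin:", cfg$thin, "\n")
  cat("Retained draws per chain:", nrow(x$draws$chains[[1]]$theta), "\n")
  invisible(x)
}
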