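#' Default demographic covariate set for the outcome submodel
#'
#' Education, income, ethnic origin, parity, age at pregnancy, and
#' gestational age at delivery. Marital status can be added by passing the
#' full column set explicitly. Categorical covariates are treatment-coded
#' against the reference levels Married, Some post-secondary, >=70k,
#' Caucasian, and parity 0.
#' @return Character vector of subject-table column names.
#' @export
jm_covariates <- function() {
  c("education", "income", "ethnicity", "parity", "age_years",
    "ga_delivery_weeks")
}

#' Prepare model data for the joint sampler
#'
#' Precomputes, per subject, the basis Gram matrix `G_i = B_i' B_i`, the
#' projection `h_i = B_i' X_i`, and the squared-norm `sum X_ij^2` (these are
#' the only data summaries the longitudinal full conditionals need), plus
#' the treatment-coded demographic design and outcome vector.
#'
#' @param cohort A `gwg_cohort` (see [read_cohort()] / [simulate_cohort()]).
#' @param grid A [changepoint_grid()].
#' @param covariates Character vector of subject-table columns entering the
#'   outcome design; `NULL` or `character(0)` for no demographics. Default
#'   [jm_covariates()].
#' @param include_self_report Include the week-0 self-reported pregravid
#'   weight as a longitudinal observation at t = 0 (default `TRUE`). With
#'   clinical observations present, shrinkage through the shared trajectory
#'   model is what corrects self-report bias.
#' @return An object of class `jm_data`: per-subject summary lists, the raw
#'   times/weights (for likelihood evaluation), design matrix `Z`, outcome
#'   `Y`, subject ids, the grid, and dimension bookkeeping.
#' @export
prepare_model_data <- function(cohort, grid, covariates = jm_covariates(),
                               include_self_report = TRUE) {
  stopifnot(inherits(cohort, "gwg_cohort"), inherits(grid, "changepoint_grid"))
  subj <- cohort$subjects
  long <- cohort$long
  if (!include_self_report) long <- long[long$source != "self_report", , drop = FALSE]
  keep <- long$subject_id %in% subj$subject_id
  long <- long[keep, , drop = FALSE]
  ids <- subj$subject_id
  n <- length(ids)
  p <- grid$K + 1L
  split_idx <- split(seq_len(nrow(long)), factor(long$subject_id, levels = ids))
  times <- weights <- vector("list", n)
  G <- array(0, c(p, p, n))
  h <- matrix(0, p, n)
  xx <- numeric(n)
  nobs <- integer(n)
  for (i in seq_len(n)) {
    idx <- split_idx[[i]]
    ti <- long$ga_weeks[idx]; xi <- long$weight_kg[idx]
    ord <- order(ti)
    times[[i]] <- ti[ord]; weights[[i]] <- xi[ord]
    nobs[i] <- length(idx)
    if (length(idx) > 0L) {
      B <- basis_row(times[[i]], grid)
      if (!is.matrix(B)) B <- matrix(B, nrow = 1L)
      G[, , i] <- crossprod(B)
      h[, i] <- crossprod(B, weights[[i]])
      xx[i] <- sum(weights[[i]]^2)
    }
  }
  if (length(covariates) > 0L) {
    missing_cols <- setdiff(covariates, names(subj))
    if (length(missing_cols) > 0L)
      stop("covariates absent from subject table: ",
           paste(missing_cols, collapse = ", "))
    Z <- stats::model.matrix(stats::reformulate(covariates), data = subj)
    Z <- Z[, -1L, drop = FALSE]
  } else {
    Z <- matrix(0, n, 0L)
  }
  structure(list(ids = ids, n = n, p = p, q = ncol(Z), grid = grid,
                 times = times, weights = weights,
                 G = G, h = h, xx = xx, nobs = nobs,
                 Z = Z, Y = subj$birth_weight_kg,
                 covariates = covariates,
                 theta_names = c("(Intercept)", colnames(Z),
                                 paste0("b", 0:grid$K), "ln_sigma_i2")),
            class = "jm_data")
}

#' Outcome linear predictor
#'
#' Computes \eqn{(1, z_i', b_i', \ln\sigma_i^2)\,\theta}, the mean of the
#' birth-weight regression for one subject.
#'
#' @param theta Outcome coefficient vector, length `1 + q + (K+1) + 1`,
#'   ordered as intercept, demographic effects, trajectory effects,
#'   log-residual-variance effect.
#' @param z Demographic covariate row (length q; may be empty).
#' @param b Subject trajectory coefficients (length K+1).
#' @param lnsig2 Subject log residual variance.
#' @return Scalar predicted birth weight (kg).
#' @export
linear_predictor <- function(theta, z, b, lnsig2) {
  x <- c(1, as.numeric(z), as.numeric(b), as.numeric(lnsig2))
  if (length(theta) != length(x))
    stop("theta has length ", length(theta), " but design row has length ",
         length(x))
  sum(theta * x)
}

#' Construct a parameter state
#'
#' Bundles the population parameters with the per-subject random effects.
#'
#' @param theta,sigma2 Outcome coefficients and residual variance.
#' @param beta,Sigma Mean and covariance of the trajectory random effects.
#' @param mu,tau2 Mean and variance of `ln sigma_i^2`.
#' @param b `(K+1) x n` matrix of subject trajectory coefficients.
#' @param lnsig2 Length-n vector of subject log residual variances.
#' @return An object of class `param_state`.
#' @export
param_state <- function(theta, sigma2, beta, Sigma, mu, tau2, b, lnsig2) {
  b <- as.matrix(b)
  if (sigma2 <= 0 || tau2 <= 0) stop("variances must be positive")
  if (nrow(b) != length(beta)) stop("b rows must match length(beta)")
  if (ncol(b) != length(lnsig2)) stop("b columns must match length(lnsig2)")
  structure(list(theta = as.numeric(theta), sigma2 = sigma2,
                 beta = as.numeric(beta), Sigma = as.matrix(Sigma),
                 mu = mu, tau2 = tau2, b = b, lnsig2 = as.numeric(lnsig2)),
            class = "param_state")
}

#' OLS-based initial parameter state
#'
#' Subject coefficients start at their OLS estimates, with the population
#' mean of the identifiable estimates substituted for unidentifiable
#' columns; residual variances at the OLS residual variance (floored);
#' population parameters at the moments of those starting values; outcome
#' coefficients at a ridge least-squares fit of Y on the initial design.
#'
#' @param mdata A [prepare_model_data()] object.
#' @param sigma2_floor Floor for initial variances (default 1e-4).
#' @return A [param_state()].
#' @export
init_state <- function(mdata, sigma2_floor = 1e-4) {
  p <- mdata$p; n <- mdata$n
  bmat <- matrix(NA_real_, p, n)
  s2 <- rep(NA_real_, n)
  fits <- vector("list", n)
  for (i in seq_len(n)) {
    f <- tryCatch(subject_ols(mdata$times[[i]], mdata$weights[[i]], mdata$grid),
                  error = function(e) NULL)
    if (!is.null(f) && !f$rank_ok) # sparse subject: ridge-stabilized start
      f <- tryCatch(subject_ols(mdata$times[[i]], mdata$weights[[i]],
                                mdata$grid, ridge = 1e-6),
                    error = function(e) NULL)
    if (!is.null(f)) {
      fits[[i]] <- f
      bmat[, i] <- f$coef
      s2[i] <- f$sigma2
    }
  }
  colmean <- apply(bmat, 1L, function(r) {
    m <- mean(r, na.rm = TRUE); if (is.nan(m)) 0 else m
  })
  for (i in seq_len(n)) {
    miss <- is.na(bmat[, i])
    bmat[miss, i] <- colmean[miss]
  }
  med <- stats::median(s2, na.rm = TRUE)
  if (!is.finite(med)) med <- 1
  s2[is.na(s2) | s2 < sigma2_floor] <- max(sigma2_floor, med)
  lnsig2 <- log(pmax(s2, sigma2_floor))
  beta <- rowMeans(bmat)
  # Moment-matched start for Sigma: the scatter of the OLS estimates
  # overstates the between-subject covariance by the average estimation
  # noise, so subtract it and clip the eigenvalues to stay PD. Sparse
  # late-gestation hinge columns otherwise seed Sigma with enormous
  # OLS-noise variances.
  Sigma <- stats::cov(t(bmat))
  if (anyNA(Sigma)) Sigma <- diag(1, p)  # single-subject start
  noise <- matrix(0, p, p)
  nuse <- 0L
  for (i in seq_len(n)) {
    f <- fits[[i]]
    if (!is.null(f) && !anyNA(f$cov)) {
      noise <- noise + f$cov
      nuse <- nuse + 1L
    }
  }
  if (nuse > 0L) {
    es <- eigen(Sigma - noise / nuse, symmetric = TRUE)
    Sigma <- es$vectors %*% diag(pmax(es$values, 1e-4), p) %*% t(es$vectors)
    Sigma <- (Sigma + t(Sigma)) / 2
  }
  Sigma <- Sigma + diag(max(1e-4, 1e-6 * mean(diag(Sigma))), p)
  W <- cbind(1, mdata$Z, t(bmat), lnsig2)
  d <- ncol(W)
  theta <- drop(solve(crossprod(W) + diag(1e-6, d), crossprod(W, mdata$Y)))
  res <- mdata$Y - drop(W %*% theta)
  sigma2 <- max(sigma2_floor, sum(res^2) / max(1L, n - d))
  mu <- mean(lnsig2)
  tau2 <- stats::var(lnsig2)
  if (!is.finite(tau2)) tau2 <- 0
  tau2 <- max(1e-3, tau2)
  param_state(theta, sigma2, beta, Sigma, mu, tau2, bmat, lnsig2)
}

#' Joint log-density of parameters, random effects, and data
#'
#' Evaluates the log of the full joint density: independent priors on
#' `theta, sigma2, beta, Sigma, mu, tau2`, plus for each subject the
#' Gaussian random-effects term `N(b_i; beta, Sigma)`, the longitudinal
#' Gaussian likelihood, the log-normal term for `sigma_i^2` (normal in
#' `ln sigma_i^2`), and the outcome Gaussian term. Normalizing constants
#' are included (full log-densities).
#'
#' @param state A [param_state()].
#' @param mdata A [prepare_model_data()] object.
#' @param priors A [prior_spec()].
#' @return Scalar log density; an error if `Sigma` is not positive definite.
#' @export
log_joint <- function(state, mdata, priors) {
  stopifnot(inherits(state, "param_state"), inherits(mdata, "jm_data"),
            inherits(priors, "prior_spec"))
  p <- mdata$p; n <- mdata$n
  ch <- tryCatch(chol(state$Sigma), error = function(e) NULL)
  if (is.null(ch)) stop("Sigma is not positive definite")
  ldet <- 2 * sum(log(diag(ch)))
  Sinv <- chol2inv(ch)
  lp <- sum(stats::dnorm(state$theta, 0, sqrt(priors$theta_var), log = TRUE)) +
    sum(stats::dnorm(state$beta, 0, sqrt(priors$beta_var), log = TRUE)) +
    ldinvgamma(state$sigma2, priors$sigma2_shape, priors$sigma2_rate) +
    stats::dnorm(state$mu, priors$mu_mean, sqrt(priors$mu_var), log = TRUE) +
    ldinvgamma(state$tau2, priors$tau2_shape, priors$tau2_rate)
  lp <- lp + if (priors$sigma_prior == "wishart")
    ldwishart(state$Sigma, priors$wishart_df, priors$Lambda)
  else
    ldinvwishart(state$Sigma, priors$wishart_df, priors$Lambda)
  for (i in seq_len(n)) {
    bi <- state$b[, i]
    dev <- bi - state$beta
    lp <- lp - 0.5 * (ldet + p * log(2 * pi) + drop(crossprod(dev, Sinv %*% dev)))
    sig2i <- exp(state$lnsig2[i])
    if (mdata$nobs[i] > 0L) {
      fit <- evaluate_trajectory(mdata$times[[i]], bi, mdata$grid)
      lp <- lp + sum(stats::dnorm(mdata$weights[[i]], fit, sqrt(sig2i),
                                  log = TRUE))
    }
    lp <- lp + stats::dnorm(state$lnsig2[i], state$mu, sqrt(state$tau2),
                            log = TRUE)
    eta <- linear_predictor(state$theta, mdata$Z[i, ], bi, state$lnsig2[i])
    lp <- lp + stats::dnorm(mdata$Y[i], eta, sqrt(state$sigma2), log = TRUE)
  }
  lp
}
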