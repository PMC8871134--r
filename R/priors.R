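#' Prior specification for the joint model
#'
#' Collects the hyperparameters of the (by default diffuse) priors:
#' `theta ~ N(0, theta_var * I)`, `beta ~ N(0, beta_var * I)`,
#' `sigma2 ~ Inv-Gamma(sigma2_shape, sigma2_rate)`,
#' `ln sigma_i^2 ~ N(mu, tau2)` with `mu ~ N(mu_mean, mu_var)` and
#' `tau2 ~ Inv-Gamma(tau2_shape, tau2_rate)`, and a Wishart prior on the
#' random-effect covariance. Two parameterizations of the covariance prior
#' are supported: `"wishart"` places a Wishart(m, Lambda) density on the
#' covariance matrix itself (non-conjugate; sampled by a
#' Metropolis-within-Gibbs step), while `"invwishart"` places a conjugate
#' inverse-Wishart(m, Lambda) prior on it.
#'
#' The inverse-gamma is parameterized by shape and rate, so
#' Inv-Gamma(1e-4, 1e-4) is the usual diffuse choice.
#'
#' @param grid A [changepoint_grid()]; fixes the dimension of `Lambda`.
#' @param theta_var,beta_var Prior variances for outcome and mean-trajectory
#'   coefficients (default 10).
#' @param sigma2_shape,sigma2_rate Inverse-gamma hyperparameters for the
#'   outcome residual variance (default 1e-4, 1e-4).
#' @param mu_mean,mu_var Normal hyperparameters for the mean of
#'   `ln sigma_i^2` (default 0, 1e3).
#' @param tau2_shape,tau2_rate Inverse-gamma hyperparameters for the
#'   variance of `ln sigma_i^2` (default 1e-4, 1e-4).
#' @param wishart_df Degrees of freedom m of the covariance prior; default
#'   `K + 3` (= dimension + 2), the standard weakly-informative choice that
#'   keeps the density proper (m > K).
#' @param Lambda Scale matrix of the covariance prior; typically produced
#'   by [empirical_bayes_wishart()]. Defaults to the identity.
#' @param sigma_prior `"wishart"` (default) or `"invwishart"`.
#' @return An object of class `prior_spec`.
#' @export
prior_spec <- function(grid,
                       theta_var = 10, beta_var = 10,
                       sigma2_shape = 1e-4, sigma2_rate = 1e-4,
                       mu_mean = 0, mu_var = 1e3,
                       tau2_shape = 1e-4, tau2_rate = 1e-4,
                       wishart_df = grid$K + 3,
                       Lambda = diag(grid$K + 1),
                       sigma_prior = c("wishart", "invwishart")) {
  stopifnot(inherits(grid, "changepoint_grid"))
  sigma_prior <- match.arg(sigma_prior)
  p <- grid$K + 1L
  Lambda <- as.matrix(Lambda)
  if (!all(dim(Lambda) == p)) stop("Lambda must be ", p, " x ", p)
  if (max(abs(Lambda - t(Lambda))) > 1e-8 * (1 + max(abs(Lambda))))
    stop("Lambda must be symmetric")
  if (wishart_df <= grid$K)
    stop("wishart_df must exceed K for a proper density")
  if (theta_var <= 0 || beta_var <= 0 || mu_var <= 0)
    stop("prior variances must be positive")
  structure(list(grid = grid, theta_var = theta_var, beta_var = beta_var,
                 sigma2_shape = sigma2_shape, sigma2_rate = sigma2_rate,
                 mu_mean = mu_mean, mu_var = mu_var,
                 tau2_shape = tau2_shape, tau2_rate = tau2_rate,
                 wishart_df = wishart_df, Lambda = (Lambda + t(Lambda)) / 2,
                 sigma_prior = sigma_prior),
            class = "prior_spec")
}

#' Empirical-Bayes Wishart scale from per-subject OLS fits
#'
#' Assembles the scale matrix `Lambda` of the covariance prior from the
#' per-subject OLS covariance estimates. The default parse sums, over
#' subjects, the inverse of each subject's covariance estimate computed on
#' that subject's identifiable columns (a subject contributes zero
#' precision on columns it cannot identify). Diagonal entries that receive
#' no contribution from any subject (e.g. a terminal hinge past every
#' observed gestational age) are filled with the mean contributing
#' diagonal value so that `Lambda` stays positive definite; these
#' components are prior-dominated and flagged.
#'
#' @param ols_fits List of [subject_ols()] fits.
#' @param grid A [changepoint_grid()].
#' @param parse `"sum_of_inverses"` (default, literal reading) or
#'   `"inverse_of_sum"` (inverse of the summed covariance estimates).
#' @param normalize Divide the result by the number of contributing
#'   subjects (default `FALSE`).
#' @param wishart_df Degrees of freedom to record (default `K + 3`).
#' @param sigma_prior Covariance-prior parameterization, forwarded to
#'   [prior_spec()]; also sets the scale of the fallback diagonal (below).
#' @param ... Further arguments passed to [prior_spec()].
#' @return A `prior_spec` whose `Lambda` and `wishart_df` are set; the
#'   attribute `"prior_dominated"` marks columns with no data contribution.
#'   Such columns (e.g. a terminal hinge past every observed gestational
#'   age) get a fallback diagonal chosen so that the implied prior mean of
#'   that variance component equals the pooled per-subject OLS variance of
#'   the identified slope components, keeping the prior proper and modest
#'   where the data are silent.
#' @export
empirical_bayes_wishart <- function(ols_fits, grid,
                                    parse = c("sum_of_inverses", "inverse_of_sum"),
                                    normalize = FALSE,
                                    wishart_df = grid$K + 3,
                                    sigma_prior = c("wishart", "invwishart"),
                                    ...) {
  sigma_prior <- match.arg(sigma_prior)
  stopifnot(inherits(grid, "changepoint_grid"))
  parse <- match.arg(parse)
  p <- grid$K + 1L
  usable <- Filter(function(f) f$rank_ok && !is.na(f$sigma2) && f$sigma2 > 0,
                   ols_fits)
  if (length(usable) == 0L)
    stop("no subject OLS fit is usable for the empirical-Bayes prior; ",
         "supply Lambda manually via prior_spec()")
  acc <- matrix(0, p, p)
  touched <- rep(FALSE, p)
  for (f in usable) {
    idx <- which(f$identifiable)
    block <- f$cov[idx, idx, drop = FALSE]
    if (parse == "sum_of_inverses") {
      binv <- tryCatch(solve(block), error = function(e) NULL)
      if (is.null(binv)) next
      acc[idx, idx] <- acc[idx, idx] + (binv + t(binv)) / 2
    } else {
      acc[idx, idx] <- acc[idx, idx] + block
    }
    touched[idx] <- TRUE
  }
  if (!any(touched)) stop("no usable precision contributions")
  if (parse == "inverse_of_sum") {
    sub <- which(touched)
    inv <- solve(acc[sub, sub, drop = FALSE])
    acc[,] <- 0
    acc[sub, sub] <- (inv + t(inv)) / 2
  }
  if (normalize) acc <- acc / length(usable)
  # Pooled fallback keeps Lambda PD when a column is empty for every
  # subject: target a prior mean equal to the pooled per-subject OLS
  # variance v0 of the identified slope components (Wishart mean m*Lambda;
  # inverse-Wishart mean Lambda/(m - p - 1)).
  if (any(!touched)) {
    v0 <- mean(unlist(lapply(usable, function(f) {
      idx <- which(f$identifiable)
      idx <- idx[idx > 1L]
      if (length(idx) == 0L) idx <- which(f$identifiable)
      diag(f$cov)[idx]
    })))
    fill <- if (sigma_prior == "wishart") v0 / wishart_df
            else v0 * max(wishart_df - p - 1, 1)
    for (k in which(!touched)) acc[k, k] <- fill
  }
  spec <- prior_spec(grid, wishart_df = wishart_df, Lambda = acc,
                     sigma_prior = sigma_prior, ...)
  attr(spec, "prior_dominated") <- !touched
  spec
}

## log-density helpers (shape/rate inverse-gamma; Wishart/inverse-Wishart)

ldinvgamma <- function(x, shape, rate) {
  shape * log(rate) - lgamma(shape) - (shape + 1) * log(x) - rate / x
}

lmvgamma <- function(a, p) {
  p * (p - 1) / 4 * log(pi) + sum(lgamma(a + (1 - seq_len(p)) / 2))
}

ldwishart <- function(W, df, S) {
  p <- nrow(W)
  chS <- chol(S); chW <- chol(W)
  ldS <- 2 * sum(log(diag(chS))); ldW <- 2 * sum(log(diag(chW)))
  (df - p - 1) / 2 * ldW - sum(diag(solve(S, W))) / 2 -
    df * p / 2 * log(2) - df / 2 * ldS - lmvgamma(df / 2, p)
}

ldinvwishart <- function(W, df, S) {
  p <- nrow(W)
  ldS <- 2 * sum(log(diag(chol(S)))); ldW <- 2 * sum(log(diag(chol(W))))
  df / 2 * ldS - (df + p + 1) / 2 * ldW - sum(diag(solve(W, S))) / 2 -
    df * p / 2 * log(2) - lmvgamma(df / 2, p)
}
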