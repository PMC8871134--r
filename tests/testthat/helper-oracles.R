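# Independent numerical oracles used across tests.

# first two moments of an unnormalized 1-D log-density via adaptive
# quadrature (normalizer computed from the same integrand)
quad_moments_1d <- function(logf, lower, upper) {
  shift <- stats::optimize(logf, c(lower, upper), maximum = TRUE)$objective
  f <- function(x) exp(logf(x) - shift)
  z <- stats::integrate(f, lower, upper, rel.tol = 1e-12)$value
  m1 <- stats::integrate(function(x) x * f(x), lower, upper,
                         rel.tol = 1e-12)$value / z
  m2 <- stats::integrate(function(x) (x - m1)^2 * f(x), lower, upper,
                         rel.tol = 1e-12)$value / z
  list(mean = m1, var = m2)
}

# moments of an unnormalized 2-D log-density on a fine Riemann grid;
# `logf` must be vectorized over both arguments
quad_moments_2d <- function(logf, xlim, ylim, n = 400) {
  xs <- seq(xlim[1], xlim[2], length.out = n)
  ys <- seq(ylim[1], ylim[2], length.out = n)
  lf <- outer(xs, ys, logf)
  w <- exp(lf - max(lf))
  w <- w / sum(w)
  mx <- sum(outer(xs, rep(1, n)) * w)
  my <- sum(outer(rep(1, n), ys) * w)
  vx <- sum((outer(xs, rep(1, n)) - mx)^2 * w)
  vy <- sum((outer(rep(1, n), ys) - my)^2 * w)
  cxy <- sum((outer(xs, rep(1, n)) - mx) * (outer(rep(1, n), ys) - my) * w)
  list(mean = c(mx, my), cov = matrix(c(vx, cxy, cxy, vy), 2))
}

# classic two-sample-style KS distance between draws and a discrete grid CDF
ks_distance_grid <- function(draws, lambda, cdf) {
  F_emp <- stats::ecdf(draws)
  max(abs(F_emp(lambda) - cdf))
}
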