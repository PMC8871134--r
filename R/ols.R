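#' Per-subject ordinary least squares trajectory fit
#'
#' Fits the truncated-linear basis to one subject's longitudinal weights by
#' OLS. Basis columns that are identically zero over the subject's
#' observation times (no observations past the corresponding knot) carry no
#' information and are flagged unidentifiable and excluded from the solve.
#' The returned covariance estimate is the residual variance times the
#' inverse Gram matrix on the identifiable columns, embedded in a full
#' (K+1) x (K+1) matrix with zero rows/columns elsewhere.
#'
#' Used for sampler initialization and for assembling the empirical-Bayes
#' Wishart scale from per-subject precision contributions.
#'
#' @param times Observation gestational ages (weeks).
#' @param weights Observed weights (kg), same length as `times`.
#' @param grid A [changepoint_grid()].
#' @param ridge Optional non-negative ridge added to the Gram diagonal for
#'   near-singular designs (default 0: plain OLS with column dropping).
#' @return An object of class `subject_ols` with elements `coef` (length
#'   K+1, `NA` on unidentifiable columns), `cov` ((K+1) x (K+1)), `sigma2`
#'   (residual variance estimate, `NA` when no residual degrees of
#'   freedom), `identifiable` (logical mask), `rank_ok` (TRUE when the
#'   identifiable design has full column rank), `n` (observation count).
#' @export
subject_ols <- function(times, weights, grid, ridge = 0) {
  stopifnot(inherits(grid, "changepoint_grid"), length(times) == length(weights))
  if (length(times) < 1L) stop("at least one observation required")
  p <- grid$K + 1L
  B <- basis_row(times, grid)
  if (!is.matrix(B)) B <- matrix(B, nrow = 1L)
  identifiable <- colSums(B != 0) > 0
  if (!any(identifiable)) stop("no identifiable basis columns for this subject")
  Bi <- B[, identifiable, drop = FALSE]
  G <- crossprod(Bi) + diag(ridge, ncol(Bi))
  qrG <- qr(G)
  rank_ok <- qrG$rank == ncol(Bi)
  coef <- rep(NA_real_, p)
  covm <- matrix(0, p, p)
  sigma2 <- NA_real_
  if (rank_ok) {
    bi <- solve(qrG, crossprod(Bi, weights))
    coef[identifiable] <- bi
    res <- weights - drop(Bi %*% bi)
    dfree <- length(times) - ncol(Bi)
    if (dfree > 0) sigma2 <- sum(res^2) / dfree
    Ginv <- solve(qrG, diag(ncol(Bi)))
    if (!is.na(sigma2)) covm[identifiable, identifiable] <- sigma2 * (Ginv + t(Ginv)) / 2
  }
  structure(list(coef = coef, cov = covm, sigma2 = sigma2,
                 identifiable = identifiable, rank_ok = rank_ok,
                 n = length(times)),
            class = "subject_ols")
}
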