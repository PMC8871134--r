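#' Changepoint grid for the piecewise-linear trajectory basis
#'
#' A trajectory is modeled as \eqn{f(t; b) = b_0 + \sum_{k=1}^K b_k (t - t_k^*)_+},
#' a linear spline in gestational age \eqn{t} (weeks) with truncated-linear
#' hinges at an increasing knot sequence starting at \eqn{t_1^* = 0}. The
#' coefficient \eqn{b_0} is the pregravid (week-0) weight and \eqn{b_k}
#' (k >= 1) is the change in weight-gain rate at knot \eqn{t_k^*}, so the
#' rate on interval \eqn{[t_k^*, t_{k+1}^*)} is the partial sum
#' \eqn{\sum_{j \le k} b_j}.
#'
#' @param knots Strictly increasing gestational ages in weeks; the first
#'   knot must be 0. Defaults to the standard grid at trimester-motivated
#'   boundaries 0, 13, 18, 23, 27, 32, 37, 45 (K = 8).
#' @return An object of class `changepoint_grid` with elements `knots` and
#'   `K` (number of slope terms; the basis dimension is `K + 1`).
#' @export
#' @examples
#' g <- changepoint_grid()
#' basis_row(20, g)
changepoint_grid <- function(knots = c(0, 13, 18, 23, 27, 32, 37, 45)) {
  knots <- as.numeric(knots)
  if (length(knots) < 1L || anyNA(knots))
    stop("knots must be a non-empty numeric vector")
  if (knots[1L] != 0)
    stop("first knot must be 0 (t_1* = 0)")
  if (is.unsorted(knots, strictly = TRUE))
    stop("knots must be strictly increasing")
  structure(list(knots = knots, K = length(knots)), class = "changepoint_grid")
}

#' Alternative convenience knot grid
#'
#' The secondary grid 0, 15, 20, 25, 30, 35, 45 (K = 6) used for
#' changepoint-sensitivity analysis.
#' @return A `changepoint_grid`.
#' @export
changepoint_grid_alt <- function() changepoint_grid(c(0, 15, 20, 25, 30, 35, 45))

#' @export
print.changepoint_grid <- function(x, ...) {
  cat("Changepoint grid: K =", x$K, "slopes, knots (weeks):",
      paste(x$knots, collapse = ", "), "\n")
  invisible(x)
}

#' Basis row of the truncated-linear spline
#'
#' Returns the length-(K+1) design row \eqn{(1, (t - t_1^*)_+, \dots,
#' (t - t_K^*)_+)} at gestational age `t`. An observation exactly at a knot
#' has hinge value 0 there (half-open interval convention).
#'
#' @param t Gestational age(s) in weeks, non-negative.
#' @param grid A [changepoint_grid()].
#' @return For scalar `t` a numeric vector of length K+1; for vector `t` a
#'   matrix with one row per time.
#' @export
basis_row <- function(t, grid) {
  stopifnot(inherits(grid, "changepoint_grid"))
  t <- as.numeric(t)
  if (anyNA(t) || any(t < 0)) stop("gestational age t must be >= 0")
  B <- cbind(1, pmax(outer(t, grid$knots, "-"), 0))
  colnames(B) <- c("b0", paste0("b", seq_len(grid$K)))
  if (length(t) == 1L) drop(B) else B
}

#' Evaluate a piecewise-linear trajectory
#'
#' @param t Gestational age(s), weeks.
#' @param b Coefficient vector of length K+1 (intercept + slope changes).
#' @param grid A [changepoint_grid()].
#' @return Weight in kg at each `t`.
#' @export
evaluate_trajectory <- function(t, b, grid) {
  stopifnot(inherits(grid, "changepoint_grid"))
  b <- as.numeric(b)
  if (length(b) != grid$K + 1L)
    stop("b must have length K + 1 = ", grid$K + 1L)
  B <- basis_row(t, grid)
  if (is.matrix(B)) drop(B %*% b) else sum(B * b)
}

#' Per-interval weight-gain rates from slope-change coefficients
#'
#' The mean rate on interval \eqn{[t_k^*, t_{k+1}^*)} is the cumulative sum
#' \eqn{\sum_{j=1}^k b_j}; successive differences of the returned vector
#' recover `b[-1]`.
#'
#' @param b Coefficient vector of length K+1.
#' @return Numeric vector of length K of rates (kg/week), one per interval.
#' @export
interval_slopes <- function(b) {
  b <- as.numeric(b)
  if (length(b) < 2L) stop("b must have length K + 1 with K >= 1")
  cumsum(b[-1L])
}

#' Slope-change coefficients from per-interval rates
#'
#' Inverse of [interval_slopes()] for the slope part: returns the length-K
#' vector of rate increments whose cumulative sums are `rates`.
#' @param rates Per-interval rates, length K.
#' @return Length-K vector of slope changes (`b[2..K+1]`).
#' @export
slope_increments <- function(rates) {
  rates <- as.numeric(rates)
  diff(c(0, rates))
}
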