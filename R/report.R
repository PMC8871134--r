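#' Gelman-Rubin potential scale reduction factor
#'
#' Classic (non-split) PSRF for one parameter from m >= 2 chains of equal
#' length n: with chain variances `s_j^2`, within-chain variance
#' `W = mean(s_j^2)`, between-chain variance `B = n * var(chain means)`,
#' the pooled estimate is `V = (n-1)/n * W + B/n` and
#' `PSRF = sqrt(V / W)`. Computed on thinned, post-burn-in draws.
#'
#' @param chains List (or matrix columns) of equal-length numeric draw
#'   vectors, one per chain.
#' @return Scalar PSRF.
#' @export
gelman_rubin <- function(chains) {
  if (is.matrix(chains)) chains <- lapply(seq_len(ncol(chains)),
                                          function(j) chains[, j])
  m <- length(chains)
  if (m < 2L) stop("at least two chains required for the PSRF")
  n <- unique(lengths(chains))
  if (length(n) != 1L) stop("chains must have equal retained lengths")
  if (n < 2L) stop("chains must have at least two draws")
  means <- vapply(chains, mean, 0)
  W <- mean(vapply(chains, stats::var, 0))
  B <- n * stats::var(means)
  V <- (n - 1) / n * W + B / n
  sqrt(V / W)
}

#' PSRF table for the outcome coefficients of a fit
#'
#' With `parameters = "all"`, every raw outcome coefficient is diagnosed.
#' With `"reported"`, the diagnostic covers the quantities the summary
#' table reports: demographic effects, the pregravid-weight effect `b0`,
#' the residual-variance effect, and the per-interval cumulative rate
#' effects (the terminal slope change, which no data inform, is excluded
#' along with the intercept).
#'
#' @param fit A `jm_fit` or `jm_draws`.
#' @param parameters `"all"` (default) or `"reported"`.
#' @return Data frame (parameter, psrf).
#' @export
psrf_table <- function(fit, parameters = c("all", "reported")) {
  parameters <- match.arg(parameters)
  if (inherits(fit, "jm_fit")) fit <- fit$draws
  stopifnot(inherits(fit, "jm_draws"))
  if (length(fit$chains) < 2L) stop("at least two chains required")
  nm <- fit$theta_names
  if (parameters == "all") {
    psrf <- vapply(seq_along(nm), function(j)
      gelman_rubin(lapply(fit$chains, function(ch) ch$theta[, j])), 0)
    return(data.frame(parameter = nm, psrf = psrf))
  }
  K <- fit$grid$K
  kk <- seq_len(K - 1L)
  direct <- c(setdiff(nm, c("(Intercept)", paste0("b", 0:K),
                            "ln_sigma_i2")),
              "b0", "ln_sigma_i2")
  labs <- sprintf("rate [%g,%g)", fit$grid$knots[kk], fit$grid$knots[kk + 1L])
  chain_cols <- function(ch) {
    cum <- t(apply(ch$theta[, paste0("b", seq_len(K)), drop = FALSE], 1L,
                   cumsum))[, kk, drop = FALSE]
    cbind(ch$theta[, direct, drop = FALSE], cum)
  }
  mats <- lapply(fit$chains, chain_cols)
  psrf <- vapply(seq_len(ncol(mats[[1L]])), function(j)
    gelman_rubin(lapply(mats, function(m) m[, j])), 0)
  data.frame(parameter = c(direct, labs), psrf = psrf)
}

#' Equal-tailed credible interval
#'
#' Empirical quantiles at `(1 - level)/2` and `1 - (1 - level)/2` using the
#' linear-interpolation quantile convention (R type 7).
#'
#' @param draws Numeric draw vector (>= 2 draws).
#' @param level Interval level (default 0.95).
#' @return Numeric `c(lower, upper)`.
#' @export
credible_interval <- function(draws, level = 0.95) {
  if (length(draws) < 2L) stop("at least two draws required")
  a <- (1 - level) / 2
  unname(stats::quantile(draws, c(a, 1 - a), type = 7))
}

#' Per-interval cumulative rate effects from outcome-coefficient draws
#'
#' Under the slope-change parameterization the coefficient on `b_k` is the
#' effect of the rate *increment* at knot k. For reporting, each retained
#' draw is transformed to the partial sums `sum_{j<=k} theta_{b_j}` for
#' k = 1..K-1 (default `"cumulative"` mode; the terminal slope change is
#' excluded). The alternative `"difference"` mode emits
#' `theta_{b_k} - theta_{b_{k+1}}`, the marginal effect of raising only
#' interval k's rate while holding the others fixed.
#'
#' @param fit A `jm_fit`, `jm_draws`, or a draws matrix whose columns
#'   include `b1..bK`.
#' @param grid The [changepoint_grid()] (taken from the fit when omitted).
#' @param mode `"cumulative"` (default) or `"difference"`.
#' @param level Credible level for the summaries.
#' @return List with `draws` (matrix, one column per gestational interval)
#'   and `summary` (data frame: interval, estimate, lower, upper,
#'   excludes_zero).
#' @export
cumulative_rate_effects <- function(fit, grid = NULL,
                                    mode = c("cumulative", "difference"),
                                    level = 0.95) {
  mode <- match.arg(mode)
  if (inherits(fit, "jm_fit")) {
    grid <- fit$mdata$grid
    theta <- pooled_draws(fit, "theta")
  } else if (inherits(fit, "jm_draws")) {
    grid <- fit$grid
    theta <- pooled_draws(fit, "theta")
  } else {
    theta <- as.matrix(fit)
    if (is.null(grid)) stop("grid required when passing a raw draws matrix")
  }
  K <- grid$K
  cols <- paste0("b", seq_len(K))
  if (!all(cols %in% colnames(theta)))
    stop("draws lack slope-effect columns ", paste(cols, collapse = ", "))
  tb <- theta[, cols, drop = FALSE]
  kk <- seq_len(K - 1L)
  eff <- if (mode == "cumulative") {
    t(apply(tb, 1L, cumsum))[, kk, drop = FALSE]
  } else {
    tb[, kk, drop = FALSE] - tb[, kk + 1L, drop = FALSE]
  }
  labs <- sprintf("[%g,%g)", grid$knots[kk], grid$knots[kk + 1L])
  colnames(eff) <- labs
  ci <- t(apply(eff, 2L, credible_interval, level = level))
  summ <- data.frame(interval = labs, estimate = colMeans(eff),
                     lower = ci[, 1L], upper = ci[, 2L])
  summ$excludes_zero <- summ$lower > 0 | summ$upper < 0
  rownames(summ) <- NULL
  list(draws = eff, summary = summ, mode = mode)
}

#' Combined summary table for a joint-model or regression fit
#'
#' Rows ordered as: demographic effects, pre-pregnancy weight, the
#' residual-variance predictor (joint model only), then the per-interval
#' rate effects. Point estimates are posterior means (joint model) or OLS
#' coefficients (regression); the excludes-zero flag is set from the 95%
#' interval.
#'
#' @param fit A `jm_fit` or `lr_fit`.
#' @param level Interval level.
#' @param mode Rate-effect reporting mode for joint models (see
#'   [cumulative_rate_effects()]).
#' @return Data frame (parameter, estimate, lower, upper, excludes_zero).
#' @export
summary_table <- function(fit, level = 0.95, mode = "cumulative") {
  if (inherits(fit, "lr_fit")) {
    tab <- fit$coef_table
    demo <- tab[!(tab$term %in% c("(Intercept)", fit$rate_cols)), ]
    preg <- tab[tab$term == "bt0", ]
    preg$term <- "pregravid_weight (bt0)"
    rates <- tab[tab$term %in% paste0("bt", seq_len(fit$scheme$K)), ]
    rates$term <- sprintf("rate [%g,%g)",
                          fit$scheme$boundaries[-length(fit$scheme$boundaries)],
                          fit$scheme$boundaries[-1L])[
                            match(rates$term,
                                  paste0("bt", seq_len(fit$scheme$K)))]
    out <- rbind(demo, preg, rates)
    names(out)[names(out) == "term"] <- "parameter"
    rownames(out) <- NULL
    return(out)
  }
  stopifnot(inherits(fit, "jm_fit"))
  theta <- pooled_draws(fit, "theta")
  nm <- colnames(theta)
  summarize <- function(cols, labels) {
    if (length(cols) == 0L) return(NULL)
    ci <- t(apply(theta[, cols, drop = FALSE], 2L, credible_interval,
                  level = level))
    data.frame(parameter = labels, estimate = colMeans(theta[, cols,
                                                             drop = FALSE]),
               lower = ci[, 1L], upper = ci[, 2L])
  }
  K <- fit$mdata$grid$K
  zcols <- setdiff(nm, c("(Intercept)", paste0("b", 0:K), "ln_sigma_i2"))
  demo <- summarize(zcols, zcols)
  preg <- summarize("b0", "pregravid_weight (b0)")
  lnv <- summarize("ln_sigma_i2", "trajectory_residual_variance (ln sigma_i^2)")
  eff <- cumulative_rate_effects(fit, level = level, mode = mode)$summary
  rates <- data.frame(parameter = paste("rate", eff$interval),
                      estimate = eff$estimate, lower = eff$lower,
                      upper = eff$upper)
  out <- rbind(demo, preg, lnv, rates)
  out$excludes_zero <- out$lower > 0 | out$upper < 0
  rownames(out) <- NULL
  out
}

#' Trajectory plot: population mean and selected subjects
#'
#' Draws the posterior-mean population trajectory with a pointwise 95%
#' credible band, optional subject-specific posterior-mean trajectories
#' with bands and observed weights, and dotted verticals at the knots.
#'
#' @param fit A `jm_fit` whose configuration retained draws for the
#'   requested subjects (`save_b_idx` in [fit_jm()]); subjects without
#'   retained draws are drawn without bands.
#' @param subjects Integer subject indices to overlay (default none).
#' @param file Output file (`.png` or `.pdf`); `NULL` plots to the active
#'   device.
#' @param t_grid Evaluation ages (weeks).
#' @param level Band level.
#' @return Invisibly, the evaluation grid and population band.
#' @export
plot_trajectories <- function(fit, subjects = integer(0), file = NULL,
                              t_grid = seq(0, 42, by = 0.25), level = 0.95) {
  stopifnot(inherits(fit, "jm_fit"))
  grid <- fit$mdata$grid
  beta_draws <- pooled_draws(fit, "beta")
  B <- basis_row(t_grid, grid)
  curves <- beta_draws %*% t(B)
  mean_curve <- colMeans(curves)
  band <- apply(curves, 2L, credible_interval, level = level)
  if (!is.null(file)) {
    if (grepl("[.]pdf$", file)) grDevices::pdf(file, width = 7, height = 5)
    else grDevices::png(file, width = 900, height = 640)
    on.exit(grDevices::dev.off())
  }
  ylim <- range(c(band, unlist(fit$mdata$weights[subjects])))
  plot(t_grid, mean_curve, type = "n", ylim = ylim,
       xlab = "Gestational age (weeks)", ylab = "Weight (kg)",
       main = "Weight-gain trajectories")
  graphics::polygon(c(t_grid, rev(t_grid)), c(band[1L, ], rev(band[2L, ])),
                    col = grDevices::adjustcolor("steelblue", 0.25),
                    border = NA)
  graphics::abline(v = grid$knots, lty = 3, col = "grey60")
  saved <- fit$draws$chains[[1L]]$save_b_idx
  p <- fit$mdata$p
  for (s in subjects) {
    pos <- match(s, saved)
    if (!is.na(pos)) {
      cols <- (pos - 1L) * p + seq_len(p)
      bdraw <- pooled_draws(fit, "b")[, cols, drop = FALSE]
      scur <- bdraw %*% t(B)
      sband <- apply(scur, 2L, credible_interval, level = level)
      graphics::polygon(c(t_grid, rev(t_grid)),
                        c(sband[1L, ], rev(sband[2L, ])),
                        col = grDevices::adjustcolor("grey50", 0.2),
                        border = NA)
      graphics::lines(t_grid, colMeans(scur), col = "grey30")
    } else {
      bm <- fit$draws$chains[[1L]]$b_mean[, s]
      graphics::lines(t_grid, drop(B %*% bm), col = "grey30")
    }
    graphics::points(fit$mdata$times[[s]], fit$mdata$weights[[s]],
                     pch = 16, cex = 0.6, col = "grey20")
  }
  graphics::lines(t_grid, mean_curve, col = "steelblue4", lwd = 2)
  invisible(list(t = t_grid, mean = mean_curve, band = band))
}
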