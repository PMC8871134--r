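#' Gestational age interval scheme for the two-stage regression
#'
#' Contiguous half-open intervals `[t_k, t_{k+1})` with midpoints `m_k`;
#' index `k = 0` refers to pregravid (week-0) measurements with `m_0 = 0`.
#' The default boundaries 0, 13, 18, 23, 27, 32, 37, 45 give midpoints
#' 6.5, 15.5, 20.5, 25, 29.5, 34.5, 41.
#'
#' @param boundaries Strictly increasing interval boundaries (weeks),
#'   starting at 0.
#' @return An object of class `interval_scheme` with `boundaries`,
#'   `midpoints` (length K), and `K` (interval count).
#' @export
interval_scheme <- function(boundaries = c(0, 13, 18, 23, 27, 32, 37, 45)) {
  boundaries <- as.numeric(boundaries)
  if (boundaries[1L] != 0) stop("first boundary must be 0")
  if (is.unsorted(boundaries, strictly = TRUE))
    stop("boundaries must be strictly increasing")
  K <- length(boundaries) - 1L
  mids <- (boundaries[-1L] + boundaries[-length(boundaries)]) / 2
  structure(list(boundaries = boundaries, midpoints = mids, K = K),
            class = "interval_scheme")
}

#' Per-interval average weights for one subject
#'
#' `mu_0` is the mean of the week-0 (pregravid) measurements; `mu_k`
#' (k >= 1) is the arithmetic mean of the during-pregnancy weights with
#' gestational age in the k-th half-open interval (a measurement exactly at
#' a boundary belongs to the right interval). Empty intervals yield `NA`.
#'
#' @param subject_long Data frame with columns `ga_weeks`, `weight_kg` (a
#'   `source` column is not required; week-0 rows define `mu_0`).
#' @param scheme An [interval_scheme()].
#' @return Named numeric vector `mu0..muK` with `NA` for empty intervals.
#' @export
interval_means <- function(subject_long, scheme = interval_scheme()) {
  stopifnot(inherits(scheme, "interval_scheme"))
  t <- subject_long$ga_weeks
  w <- subject_long$weight_kg
  mu <- rep(NA_real_, scheme$K + 1L)
  if (any(t == 0)) mu[1L] <- mean(w[t == 0])
  for (k in seq_len(scheme$K)) {
    lo <- scheme$boundaries[k]; hi <- scheme$boundaries[k + 1L]
    sel <- t > 0 & t >= lo & t < hi
    if (any(sel)) mu[k + 1L] <- mean(w[sel])
  }
  names(mu) <- paste0("mu", 0:scheme$K)
  mu
}

#' Midpoint rate features from interval means
#'
#' `bt0 = mu_0` (average pregravid weight, kg) and
#' `bt_k = (mu_k - mu_{k-1}) / (m_k - m_{k-1})` (kg/week) with `m_0 = 0`;
#' a rate is `NA` unless both adjacent interval means are present.
#'
#' @param means Output of [interval_means()].
#' @param scheme An [interval_scheme()].
#' @return Named numeric vector `bt0..btK`.
#' @export
rate_features <- function(means, scheme = interval_scheme()) {
  stopifnot(length(means) == scheme$K + 1L)
  m <- c(0, scheme$midpoints)
  bt <- c(means[1L], diff(means) / diff(m))
  names(bt) <- paste0("bt", 0:scheme$K)
  bt
}

#' Rate-feature table for a cohort
#'
#' @param cohort A `gwg_cohort`.
#' @param scheme An [interval_scheme()].
#' @return Data frame with `subject_id` and columns `bt0..btK` (`NA` where
#'   undefined).
#' @export
lr_features <- function(cohort, scheme = interval_scheme()) {
  stopifnot(inherits(cohort, "gwg_cohort"))
  rows <- lapply(split(cohort$long, factor(cohort$long$subject_id,
                                           levels = cohort$subjects$subject_id)),
                 function(d) rate_features(interval_means(d, scheme), scheme))
  out <- data.frame(subject_id = cohort$subjects$subject_id,
                    do.call(rbind, rows), check.names = FALSE)
  rownames(out) <- NULL
  out
}

#' Fit the two-stage linear regression (LR1)
#'
#' Ordinary least squares of infant birth weight on the demographic
#' covariates, the average pregravid weight `bt0`, and the precomputed
#' interval rates `bt1..btK`, with classical t-based 95% confidence
#' intervals. Subjects missing any rate feature are dropped
#' (complete-case).
#'
#' @param cohort A `gwg_cohort`.
#' @param scheme An [interval_scheme()].
#' @param covariates Demographic covariate columns (default
#'   [jm_covariates()]).
#' @param level Confidence level (default 0.95).
#' @return An object of class `lr_fit`: the `lm` object, a coefficient
#'   table with intervals and excludes-zero flags, term bookkeeping, and
#'   `n_used` / `n_dropped`.
#' @export
fit_lr <- function(cohort, scheme = interval_scheme(),
                   covariates = jm_covariates(), level = 0.95) {
  stopifnot(inherits(cohort, "gwg_cohort"))
  feats <- lr_features(cohort, scheme)
  rate_cols <- paste0("bt", 0:scheme$K)
  dat <- cbind(cohort$subjects[, c("subject_id", covariates,
                                   "birth_weight_kg"), drop = FALSE],
               feats[, rate_cols, drop = FALSE])
  cc <- stats::complete.cases(dat)
  used <- dat[cc, , drop = FALSE]
  form <- stats::reformulate(c(covariates, rate_cols),
                             response = "birth_weight_kg")
  fit <- stats::lm(form, data = used)
  cf <- stats::coef(fit)
  if (anyNA(cf))
    stop("rank-deficient design; collinear columns: ",
         paste(names(cf)[is.na(cf)], collapse = ", "))
  ci <- stats::confint(fit, level = level)
  tab <- data.frame(term = names(cf), estimate = unname(cf),
                    lower = ci[, 1L], upper = ci[, 2L])
  tab$excludes_zero <- tab$lower > 0 | tab$upper < 0
  rownames(tab) <- NULL
  structure(list(lm = fit, coef_table = tab, covariates = covariates,
                 scheme = scheme, rate_cols = rate_cols, level = level,
                 data = used, n_used = sum(cc), n_dropped = sum(!cc)),
            class = "lr_fit")
}

#' @export
print.lr_fit <- function(x, ...) {
  cat("Two-stage linear regression:", x$n_used, "subjects used,",
      x$n_dropped, "dropped (incomplete rate features)\n")
  print(x$coef_table, digits = 3)
  invisible(x)
}

# shared pruning rule: a demographic covariate survives when any of its
# treatment-coded levels has an interval excluding zero
kept_demographics <- function(covariates, data, term_of_col, lower, upper) {
  keep <- character(0)
  for (cv in covariates) {
    cols <- which(term_of_col == cv)
    if (length(cols) == 0L) next
    if (any(lower[cols] > 0 | upper[cols] < 0)) keep <- c(keep, cv)
  }
  keep
}

# map design columns to term labels using the model.matrix assign attribute
assign_terms <- function(covariates, data) {
  mm <- stats::model.matrix(stats::reformulate(covariates), data = data)
  a <- attr(mm, "assign")
  labs <- c("(Intercept)", covariates)[a + 1L]
  stats::setNames(labs[-1L], colnames(mm)[-1L])
}

#' Prune non-significant demographics and refit (second-stage models)
#'
#' Implements the reduced-model rule shared by the regression and joint
#' approaches: only demographic covariates whose 95% interval in the
#' first-stage fit excludes zero are retained (a categorical covariate is
#' kept if any of its levels excludes zero); pregravid-weight, rate, and
#' residual-variance predictors are always retained. The model is then
#' refit with the reduced covariate set.
#'
#' @param fit An `lr_fit` or `jm_fit`.
#' @param ... Passed to the refit ([fit_lr()] or [fit_jm()]); for `jm_fit`
#'   supply `cohort` and optionally `config`.
#' @return A refit object of the same class, with attribute
#'   `"kept_covariates"`.
#' @export
prune_and_refit <- function(fit, ...) UseMethod("prune_and_refit")

#' @rdname prune_and_refit
#' @param cohort Cohort to refit on (defaults to the data stored in the
#'   fit for `lr_fit`).
#' @export
prune_and_refit.lr_fit <- function(fit, cohort = NULL, ...) {
  tm <- assign_terms(fit$covariates, fit$data)
  tab <- fit$coef_table
  idx <- match(names(tm), tab$term)
  keep <- kept_demographics(fit$covariates, fit$data, tm,
                            tab$lower[idx], tab$upper[idx])
  if (is.null(cohort)) {
    dat <- fit$data
    cohort <- gwg_cohort(dat[, setdiff(names(dat), fit$rate_cols),
                             drop = FALSE],
                         data.frame(subject_id = character(0),
                                    ga_weeks = numeric(0),
                                    weight_kg = numeric(0),
                                    source = character(0)))
    # reuse the already-computed rate features rather than re-deriving
    refit <- fit_lr_features(dat, keep, fit$scheme, fit$rate_cols, fit$level)
  } else {
    refit <- fit_lr(cohort, fit$scheme, covariates = keep,
                    level = fit$level, ...)
  }
  attr(refit, "kept_covariates") <- keep
  refit
}

# refit directly from a feature table (internal; keeps LR2 on exactly the
# LR1 estimation sample)
fit_lr_features <- function(dat, covariates, scheme, rate_cols, level) {
  form <- stats::reformulate(c(covariates, rate_cols),
                             response = "birth_weight_kg")
  fit <- stats::lm(form, data = dat)
  cf <- stats::coef(fit)
  ci <- stats::confint(fit, level = level)
  tab <- data.frame(term = names(cf), estimate = unname(cf),
                    lower = ci[, 1L], upper = ci[, 2L])
  tab$excludes_zero <- tab$lower > 0 | tab$upper < 0
  rownames(tab) <- NULL
  structure(list(lm = fit, coef_table = tab, covariates = covariates,
                 scheme = scheme, rate_cols = rate_cols, level = level,
                 data = dat, n_used = nrow(dat), n_dropped = 0L),
            class = "lr_fit")
}

#' @rdname prune_and_refit
#' @param config Optional [mcmc_config()] for the joint-model refit
#'   (defaults to the first-stage configuration).
#' @export
prune_and_refit.jm_fit <- function(fit, cohort, config = NULL, ...) {
  stopifnot(inherits(cohort, "gwg_cohort"))
  if (is.null(config)) config <- fit$draws$config
  theta <- pooled_draws(fit, "theta")
  tm <- assign_terms(fit$covariates, cohort$subjects)
  idx <- match(names(tm), colnames(theta))
  ci <- t(apply(theta[, idx, drop = FALSE], 2L, credible_interval))
  keep <- kept_demographics(fit$covariates, cohort$subjects, tm,
                            ci[, 1L], ci[, 2L])
  refit <- fit_jm(cohort, grid = fit$mdata$grid, covariates = keep,
                  config = config, ...)
  attr(refit, "kept_covariates") <- keep
  refit
}
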