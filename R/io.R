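#' Cohort container
#'
#' Bundles the subject-level table (demographics, gestational age at
#' delivery, infant birth weight) with the long-format longitudinal weight
#' table. Categorical covariates are coded as factors whose first level is
#' the reference category (Married, Some post-secondary, >=70k, Caucasian,
#' parity 0).
#'
#' @param subjects Data frame with columns `subject_id`, covariate columns,
#'   `ga_delivery_weeks`, `birth_weight_kg`.
#' @param long Data frame with columns `subject_id`, `ga_weeks`,
#'   `weight_kg`, `source` (one of `"self_report"`, `"clinical"`).
#' @param truth Optional truth ledger from [simulate_cohort()].
#' @return An object of class `gwg_cohort`.
#' @export
gwg_cohort <- function(subjects, long, truth = NULL) {
  req_s <- c("subject_id", "ga_delivery_weeks", "birth_weight_kg")
  req_l <- c("subject_id", "ga_weeks", "weight_kg", "source")
  miss <- setdiff(req_s, names(subjects))
  if (length(miss)) stop("subject table lacks columns: ",
                         paste(miss, collapse = ", "))
  miss <- setdiff(req_l, names(long))
  if (length(miss)) stop("longitudinal table lacks columns: ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(subjects$subject_id))
    stop("duplicate subject_id in subject table")
  orphan <- !(long$subject_id %in% subjects$subject_id)
  if (any(orphan))
    stop("longitudinal rows with unknown subject_id: rows ",
         paste(utils::head(which(orphan), 5L), collapse = ", "))
  bad_t <- !is.na(long$ga_weeks) & long$ga_weeks < 0
  if (any(bad_t))
    stop("negative ga_weeks in longitudinal rows: ",
         paste(utils::head(which(bad_t), 5L), collapse = ", "))
  bad_w <- !is.na(long$weight_kg) & long$weight_kg <= 0
  if (any(bad_w))
    stop("non-positive weight_kg in longitudinal rows: ",
         paste(utils::head(which(bad_w), 5L), collapse = ", "))
  bad_src <- !(long$source %in% c("self_report", "clinical"))
  if (any(bad_src))
    stop("invalid source flag in longitudinal rows: ",
         paste(utils::head(which(bad_src), 5L), collapse = ", "))
  structure(list(subjects = subjects, long = long, truth = truth),
            class = "gwg_cohort")
}

#' @export
print.gwg_cohort <- function(x, ...) {
  cat("Cohort:", nrow(x$subjects), "subjects,", nrow(x$long),
      "longitudinal observations\n")
  if (!is.null(x$truth)) cat("Truth ledger attached (synthetic cohort)\n")
  invisible(x)
}

#' Reference factor levels for the demographic covariates
#' @return Named list of level vectors (reference first).
#' @export
covariate_levels <- function() {
  list(marital_status = c("Married", "Single"),
       education = c("Some post-secondary", "Graduate degree", "High school"),
       income = c(">=70k", "<70k"),
       ethnicity = c("Caucasian", "Asian", "Black", "Latin American",
                     "Southeast Asian", "Other"),
       parity = c("0", "1", "2+"))
}

recode_covariates <- function(subjects) {
  lv <- covariate_levels()
  for (nm in names(lv)) {
    if (nm %in% names(subjects)) {
      bad <- !is.na(subjects[[nm]]) & !(subjects[[nm]] %in% lv[[nm]])
      if (any(bad))
        stop("column '", nm, "' has invalid levels: ",
             paste(unique(subjects[[nm]][bad]), collapse = ", "))
      subjects[[nm]] <- factor(subjects[[nm]], levels = lv[[nm]])
    }
  }
  subjects
}

#' Read a cohort from CSV files
#'
#' @param subjects_file CSV with the subject-level schema (see
#'   [gwg_cohort()]).
#' @param long_file CSV with the long-format longitudinal schema.
#' @param truth_file Optional truth-ledger CSV written by [write_cohort()].
#' @return A validated `gwg_cohort` with treatment-coded factors.
#' @export
read_cohort <- function(subjects_file, long_file, truth_file = NULL) {
  subjects <- utils::read.csv(subjects_file, stringsAsFactors = FALSE)
  long <- utils::read.csv(long_file, stringsAsFactors = FALSE)
  subjects <- recode_covariates(subjects)
  truth <- NULL
  if (!is.null(truth_file) && file.exists(truth_file))
    truth <- list(effects = utils::read.csv(truth_file,
                                            stringsAsFactors = FALSE))
  gwg_cohort(subjects, long, truth)
}

#' Write a cohort to CSV files
#'
#' Writes the subject and longitudinal tables (and the truth ledger, when
#' present) as plain CSV; [read_cohort()] round-trips the values.
#'
#' @param cohort A `gwg_cohort`.
#' @param subjects_file,long_file,truth_file Output paths (`truth_file`
#'   `NULL` to skip).
#' @return Invisibly, the vector of files written.
#' @export
write_cohort <- function(cohort, subjects_file, long_file,
                         truth_file = NULL) {
  stopifnot(inherits(cohort, "gwg_cohort"))
  utils::write.csv(cohort$subjects, subjects_file, row.names = FALSE)
  utils::write.csv(cohort$long, long_file, row.names = FALSE)
  written <- c(subjects_file, long_file)
  if (!is.null(truth_file) && !is.null(cohort$truth)) {
    utils::write.csv(cohort$truth$effects, truth_file, row.names = FALSE)
    written <- c(written, truth_file)
  }
  invisible(written)
}

#' Write posterior draws and metadata to disk
#'
#' One CSV per chain (one row per retained draw, columns named by
#' parameter) plus a JSON sidecar recording the configuration, seeds, and
#' knots.
#'
#' @param draws A `jm_draws` or `jm_fit`.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix (default `"chain"`).
#' @return Invisibly, the files written.
#' @export
write_draws <- function(draws, dir, prefix = "chain") {
  if (inherits(draws, "jm_fit")) draws <- draws$draws
  stopifnot(inherits(draws, "jm_draws"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  for (c in seq_along(draws$chains)) {
    ch <- draws$chains[[c]]
    theta <- ch$theta
    colnames(theta) <- paste0("theta.", colnames(theta))
    beta <- ch$beta
    colnames(beta) <- paste0("beta.", colnames(beta))
    tab <- cbind(data.frame(theta, check.names = FALSE),
                 data.frame(beta, check.names = FALSE),
                 data.frame(ch$Sigma, check.names = FALSE),
                 mu = ch$mu, tau2 = ch$tau2, sigma2 = ch$sigma2)
    f <- file.path(dir, sprintf("%s%d.csv", prefix, c))
    utils::write.csv(tab, f, row.names = FALSE)
    files <- c(files, f)
  }
  meta <- list(config = unclass(draws$config), seeds = draws$seeds,
               knots = draws$grid$knots, theta_names = draws$theta_names)
  mf <- file.path(dir, paste0(prefix, "_meta.json"))
  jsonlite::write_json(meta, mf, auto_unbox = TRUE, digits = NA)
  invisible(c(files, mf))
}

#' Read stored posterior draws
#'
#' Reads the per-chain CSVs and JSON sidecar written by [write_draws()].
#'
#' @param dir Directory containing the files.
#' @param prefix File-name prefix used when writing (default `"chain"`).
#' @return List with `chains` (data frames, one per chain) and `meta`.
#' @export
read_draws <- function(dir, prefix = "chain") {
  mf <- file.path(dir, paste0(prefix, "_meta.json"))
  if (!file.exists(mf)) stop("no metadata sidecar at ", mf)
  meta <- jsonlite::read_json(mf, simplifyVector = TRUE)
  files <- sort(list.files(dir, pattern = paste0("^", prefix, "[0-9]+\\.csv$"),
                           full.names = TRUE))
  if (length(files) == 0L) stop("no draw files with prefix '", prefix,
                                "' in ", dir)
  chains <- lapply(files, utils::read.csv, check.names = FALSE)
  list(chains = chains, meta = meta)
}
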