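# align a truth table and an estimate table into two L x N matrices
.align_prop_tables <- function(truth, estimates, populations = NULL) {
  est <- if (inherits(estimates, "cgr_fit")) estimates$proportions else as_tibble(estimates)
  tru <- as_tibble(truth)
  if (!"individual_id" %in% names(tru) || !"individual_id" %in% names(est)) {
    abort("both tables need an `individual_id` column.")
  }
  tpops <- prop_populations(tru)
  epops <- prop_populations(est)
  if (is.null(populations)) {
    populations <- epops
    if (!setequal(tpops, epops)) {
      abort(sprintf("population sets differ (truth: %s; estimates: %s); use `populations` to restrict.",
                    toString(tpops), toString(epops)))
    }
  }
  if (!length(populations)) abort("empty population restriction.")
  bad <- setdiff(populations, tpops)
  if (length(bad)) abort(sprintf("population(s) absent from truth table: %s", toString(bad)))
  bad <- setdiff(populations, epops)
  if (length(bad)) abort(sprintf("population(s) absent from estimates: %s", toString(bad)))
  if (!setequal(tru$individual_id, est$individual_id)) {
    abort("truth and estimates cover different individuals.")
  }
  tru <- tru[match(est$individual_id, tru$individual_id), ]
  list(
    truth = as.matrix(tru[populations]),
    est = as.matrix(est[populations]),
    populations = populations
  )
}

#' Evaluation metrics for estimated genome proportions
#'
#' Compares estimated against true proportions over all individual-by-
#' population cells and reports:
#' \describe{
#'   \item{max_abs_error}{maximum of the absolute cell differences (MAX).}
#'   \item{bias}{signed mean of (true - estimated).}
#'   \item{mse}{mean squared difference.}
#'   \item{mae}{mean absolute difference (better suited to plotting than
#'     the MSE).}
#'   \item{correlation}{Pearson correlation of the flattened cell vectors,
#'     centred at the single grand means of each side (equivalent to the
#'     textbook Pearson correlation of the flattened vectors). Reported as
#'     `NA` with a warning when either side has zero variance.}
#' }
#'
#' @param truth wide tibble of true proportions (`individual_id` + one column
#'   per population).
#' @param estimates a [cgr_estimate()] fit or a wide proportions tibble
#'   covering the same individuals.
#' @param populations optional character vector restricting the scored cells
#'   to a subset of populations — used by under-specified trials, where the
#'   omitted population's cells are not regarded, and by type-2 trials, which
#'   score only the focal column.
#' @return A one-row tibble with the fields above plus `n_individuals` and
#'   `n_populations`.
#' @export
compute_metrics <- function(truth, estimates, populations = NULL) {
  al <- .align_prop_tables(truth, estimates, populations)
  bt <- as.numeric(al$truth)
  be <- as.numeric(al$est)
  d <- bt - be
  tibble(
    max_abs_error = max(abs(d)),
    bias = mean(d),
    mse = mean(d^2),
    mae = mean(abs(d)),
    correlation = .grand_mean_cor(bt, be),
    n_individuals = nrow(al$truth),
    n_populations = length(al$populations)
  )
}

# Pearson correlation with explicit grand-mean centring over all cells
.grand_mean_cor <- function(a, b) {
  da <- a - mean(a)
  db <- b - mean(b)
  den <- sqrt(sum(da^2) * sum(db^2))
  if (den == 0) {
    warn("zero variance in a flattened proportion vector; correlation undefined.")
    return(NA_real_)
  }
  sum(da * db) / den
}

#' Categorise individuals by a true genome proportion
#'
#' Assigns each value to one of six categories of true proportion:
#' exactly 0, four quarter-bins with inclusive upper bounds, and exactly 1.
#' Boundaries are exact (simulated truths are rationals, so no epsilon is
#' applied): 0.25 falls in `">0-25%"`, 1 - 1/(2M) in `">75-<100%"`.
#'
#' @param x numeric vector of true proportions in `[0, 1]`.
#' @return A factor with levels `"0%"`, `">0-25%"`, `">25-50%"`,
#'   `">50-75%"`, `">75-<100%"`, `"100%"`.
#' @export
categorise_by_truth <- function(x) {
  if (any(x < 0 | x > 1, na.rm = TRUE) || anyNA(x)) {
    abort("true proportions must lie in [0, 1].")
  }
  lv <- c("0%", ">0-25%", ">25-50%", ">50-75%", ">75-<100%", "100%")
  out <- character(length(x))
  out[x == 0] <- lv[1]
  out[x > 0 & x <= 0.25] <- lv[2]
  out[x > 0.25 & x <= 0.5] <- lv[3]
  out[x > 0.5 & x <= 0.75] <- lv[4]
  out[x > 0.75 & x < 1] <- lv[5]
  out[x == 1] <- lv[6]
  factor(out, levels = lv)
}

#' Correlation between the estimation errors of two estimate sets
#'
#' Pearson correlation between the flattened error vectors
#' (true - estimated) of two fits of the same cohort — e.g. the two
#' constraint modes, or two different estimators. Identical estimates give 1;
#' a zero-variance error vector (e.g. a perfect fit) yields `NA` with a
#' warning.
#'
#' @param estimates_a,estimates_b two fits or wide proportion tibbles.
#' @inheritParams compute_metrics
#' @return A single correlation value.
#' @export
error_correlation <- function(estimates_a, estimates_b, truth, populations = NULL) {
  a <- .align_prop_tables(truth, estimates_a, populations)
  b <- .align_prop_tables(truth, estimates_b, a$populations)
  ea <- as.numeric(a$truth) - as.numeric(a$est)
  eb <- as.numeric(b$truth) - as.numeric(b$est)
  .grand_mean_cor(ea, eb)
}
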