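#' Fully specified trial: estimate against the complete founder panel
#'
#' Estimates every individual's genome proportions with all panel populations
#' in the design and scores them against the truth. With
#' `constraint = "both"` the trial is run under the sum-to-one and the
#' sum-at-most-one constraints and additionally reports the correlation
#' between the two modes' estimation errors (the two feasible sets differ
#' only on the boundary, so near-identical errors are expected when the
#' panel is complete).
#'
#' @param genotypes a [geno_matrix()] of admixed individuals.
#' @param truth wide tibble of true proportions for the same individuals.
#' @param panel the full [founder_panel()].
#' @param constraint `"eq"`, `"le"`, or `"both"`.
#' @return A `cgr_trial` list: `metrics` (one row per mode), `fits` (named
#'   list of [cgr_estimate()] fits), and `error_correlation` (between modes;
#'   `NA` unless both were run).
#' @export
run_full_trial <- function(genotypes, truth, panel, constraint = c("both", "eq", "le")) {
  constraint <- match.arg(constraint)
  modes <- if (constraint == "both") c("eq", "le") else constraint
  fits <- lapply(modes, function(m) cgr_estimate(genotypes, panel, constraint = m))
  names(fits) <- modes
  metrics <- dplyr::bind_rows(lapply(modes, function(m) {
    dplyr::bind_cols(tibble(constraint = m), compute_metrics(truth, fits[[m]]))
  }))
  err_r <- if (length(modes) == 2) {
    error_correlation(fits[["eq"]], fits[["le"]], truth)
  } else NA_real_
  structure(list(type = "full", metrics = metrics, fits = fits,
                 error_correlation = err_r),
            class = "cgr_trial")
}

#' Under-specified (type-1) trial: one contributing population omitted
#'
#' Drops `exclude` from the panel, estimates under the sum-at-most-one
#' constraint (the extra slack is what lets the model signal a missing
#' contributor), and scores only the remaining populations' cells — the
#' omitted population's cells are not regarded. Results are broken down by
#' the six categories of the individuals' true proportion of the omitted
#' population, and an absorption table reports, per category, the mean
#' estimated share of each remaining population together with its mean
#' excess over truth (where the omitted genome mass went).
#'
#' @inheritParams run_full_trial
#' @param exclude population name to omit from the design.
#' @param constraint constraint mode for the reduced model (default `"le"`).
#' @param full_fit optional full-model fit of the same cohort (same
#'   constraint) used for the per-category comparison columns; computed
#'   internally when `NULL`.
#' @return A `cgr_trial` list with `metrics` (scored populations only),
#'   `by_category` (per category: `n`, `correlation`, `mae`, and the
#'   full-model `mae_full`), `absorption` (category x population mean shares
#'   and excesses), and the reduced-model `fit`.
#' @export
run_type1_trial <- function(genotypes, truth, panel, exclude,
                            constraint = "le", full_fit = NULL) {
  pops <- panel_populations(panel)
  if (!exclude %in% pops) abort(sprintf("population '%s' not in panel.", exclude))
  scored <- setdiff(pops, exclude)
  sub <- subset_panel(panel, scored)
  fit <- cgr_estimate(genotypes, sub, constraint = constraint)
  if (is.null(full_fit)) {
    full_fit <- cgr_estimate(genotypes, panel, constraint = constraint)
  }
  metrics <- compute_metrics(truth, fit, populations = scored)

  cat_of <- categorise_by_truth(truth[[exclude]])
  ids_by_cat <- split(truth$individual_id, cat_of)
  per_cat <- purrr::imap(ids_by_cat, function(ids, lab) {
    if (!length(ids)) {
      return(tibble(category = lab, n = 0L, correlation = NA_real_,
                    mae = NA_real_, mae_full = NA_real_))
    }
    tr <- truth[truth$individual_id %in% ids, ]
    m_red <- compute_metrics(tr, .filter_fit(fit, ids), populations = scored)
    m_full <- compute_metrics(tr, .filter_fit(full_fit, ids), populations = scored)
    tibble(category = lab, n = length(ids),
           correlation = m_red$correlation, mae = m_red$mae,
           mae_full = m_full$mae)
  })
  by_category <- dplyr::bind_rows(per_cat)

  absorption <- purrr::imap(ids_by_cat, function(ids, lab) {
    if (!length(ids)) return(NULL)
    est <- fit$proportions[fit$proportions$individual_id %in% ids, ]
    tr <- truth[match(est$individual_id, truth$individual_id), ]
    tibble(
      category = lab,
      population = scored,
      mean_share = colMeans(as.matrix(est[scored])),
      mean_excess = colMeans(as.matrix(est[scored]) - as.matrix(tr[scored])),
      n = length(ids)
    )
  })
  absorption <- dplyr::bind_rows(absorption)

  structure(list(type = "type1", excluded = exclude, metrics = metrics,
                 by_category = by_category, absorption = absorption,
                 fit = fit, full_fit = full_fit),
            class = "cgr_trial")
}

.filter_fit <- function(fit, ids) {
  fit$proportions[fit$proportions$individual_id %in% ids, ]
}

#' Miss-specified (type-2) trial: one known founder plus a pooled background
#'
#' Restricts the cohort to individuals that truly carry some of the focal
#' population's genome, builds the two-column design of
#' [build_type2_design()] (focal column plus the mean allele content of
#' `n_background` genotypes sampled from the non-focal reference pool), fits
#' under the sum-at-most-one constraint, and scores only the focal column.
#'
#' @inheritParams run_full_trial
#' @param focal the precisely specified founder population.
#' @param pool a [geno_matrix()] of non-focal reference genotypes.
#' @param pool_labels optional labels for `pool` (to verify focal absence).
#' @param n_background background sample size (default 500).
#' @param seed optional seed for the background draw.
#' @return A `cgr_trial` list with `metrics` (focal column only), the `fit`,
#'   the two-column `design` panel, and `n_individuals` used.
#' @export
run_type2_trial <- function(genotypes, truth, panel, focal, pool,
                            pool_labels = NULL, n_background = 500, seed = NULL) {
  if (!focal %in% prop_populations(truth)) {
    abort(sprintf("population '%s' not in truth table.", focal))
  }
  keep_ids <- truth$individual_id[truth[[focal]] > 0]
  if (!length(keep_ids)) abort("no admixed individuals carry the focal population's genome.")
  design <- build_type2_design(panel, focal, pool, pool_labels,
                               n_sample = n_background, seed = seed)
  sub_geno <- subset_geno(genotypes, individuals = intersect(individual_ids(genotypes), keep_ids))
  fit <- cgr_estimate(sub_geno, design, constraint = "le")
  tr <- truth[truth$individual_id %in% individual_ids(sub_geno), ]
  metrics <- compute_metrics(tr, fit, populations = focal)
  structure(list(type = "type2", focal = focal, metrics = metrics, fit = fit,
                 design = design, n_individuals = length(keep_ids)),
            class = "cgr_trial")
}

#' @export
print.cgr_trial <- function(x, ...) {
  cat(sprintf("<cgr_trial> %s%s\n", x$type,
              switch(x$type,
                     type1 = sprintf(" (excluded: %s)", x$excluded),
                     type2 = sprintf(" (focal: %s)", x$focal),
                     "")))
  print(x$metrics)
  invisible(x)
}

#' @method glance cgr_trial
#' @export
glance.cgr_trial <- function(x, ...) x$metrics

#' @method tidy cgr_trial
#' @export
tidy.cgr_trial <- function(x, ...) {
  if (x$type == "type1") x$by_category else x$metrics
}
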