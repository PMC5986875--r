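#' Founder allele-frequency panel
#'
#' Holds the per-population frequencies \eqn{p_{i,k}} of the counted allele at
#' each marker, together with the design matrix \eqn{X} whose column
#' \eqn{k} is the expected allele content \eqn{2 p_{\cdot,k}} under
#' Hardy-Weinberg equilibrium. `X` is what the constrained regression fits
#' against; it always equals `2 * freqs` exactly.
#'
#' @param freqs numeric matrix of allele frequencies in `[0, 1]`, markers in
#'   rows (rownames = marker ids), populations in columns (colnames).
#' @param alleles optional allele-label tibble as in [geno_matrix()], recording
#'   which allele the frequencies count.
#' @return An object of class `founder_panel` with elements `freqs`, `design`,
#'   and `alleles`.
#' @export
founder_panel <- function(freqs, alleles = NULL) {
  if (!is.matrix(freqs)) abort("`freqs` must be a matrix.")
  if (is.null(rownames(freqs)) || is.null(colnames(freqs))) {
    abort("`freqs` needs marker rownames and population colnames.")
  }
  if (ncol(freqs) < 1) abort("a panel needs at least one population.")
  if (any(!is.finite(freqs)) || any(freqs < 0) || any(freqs > 1)) {
    abort("allele frequencies must lie in [0, 1].")
  }
  structure(list(freqs = freqs, design = 2 * freqs, alleles = alleles),
            class = "founder_panel")
}

#' @export
print.founder_panel <- function(x, ...) {
  cat(sprintf("<founder_panel> %d markers x %d populations: %s\n",
              nrow(x$freqs), ncol(x$freqs), toString(colnames(x$freqs))))
  invisible(x)
}

#' @export
dim.founder_panel <- function(x) dim(x$freqs)

#' Population names of a panel
#' @param panel a [founder_panel()].
#' @export
panel_populations <- function(panel) colnames(panel$freqs)

#' @describeIn founder_panel long view: one row per (marker, population)
#'   with `freq` and expected allele `content`.
#' @param x a `founder_panel`.
#' @param ... unused.
#' @method as_tibble founder_panel
#' @export
as_tibble.founder_panel <- function(x, ...) {
  tibble(
    marker_id = rep(rownames(x$freqs), times = ncol(x$freqs)),
    population = rep(colnames(x$freqs), each = nrow(x$freqs)),
    freq = as.numeric(x$freqs),
    content = as.numeric(x$design)
  )
}

#' @method tidy founder_panel
#' @export
tidy.founder_panel <- function(x, ...) as_tibble(x)

#' Estimate founder allele frequencies from labelled reference genotypes
#'
#' The frequency of the counted allele in population \eqn{k} at marker
#' \eqn{i} is the plain mean dosage over that population's non-missing
#' genotypes divided by two — no pseudo-counts or shrinkage, since the
#' regression treats founder frequencies as known constants.
#'
#' @param reference a [geno_matrix()] of reference individuals.
#' @param labels tibble with columns `individual_id`, `population`; every
#'   labelled individual must be present in `reference`. Population order in
#'   the panel follows first appearance in `labels`.
#' @param maf_min,maf_max optional across-reference frequency filter: markers
#'   with overall counted-allele frequency outside `[maf_min, maf_max]` are
#'   dropped before estimation (e.g. 0.01 and 0.99).
#' @return A [founder_panel()].
#' @export
estimate_frequencies <- function(reference, labels, maf_min = NULL, maf_max = NULL) {
  stopifnot(inherits(reference, "geno_matrix"))
  miss <- setdiff(labels$individual_id, individual_ids(reference))
  if (length(miss)) {
    abort(sprintf("labelled individuals absent from reference: %s", toString(head(miss, 5))))
  }
  counts <- reference$counts[, labels$individual_id, drop = FALSE]
  if (!is.null(maf_min) || !is.null(maf_max)) {
    overall <- rowMeans(counts, na.rm = TRUE) / 2
    keep <- (is.null(maf_min) | overall >= (maf_min %||% 0)) &
            (is.null(maf_max) | overall <= (maf_max %||% 1))
    keep[is.na(keep)] <- FALSE
    counts <- counts[keep, , drop = FALSE]
    if (!nrow(counts)) abort("all markers removed by the frequency filter.")
  }
  pops <- unique(labels$population)
  freqs <- matrix(NA_real_, nrow(counts), length(pops),
                  dimnames = list(rownames(counts), pops))
  for (k in pops) {
    sub <- counts[, labels$population == k, drop = FALSE]
    n_obs <- rowSums(!is.na(sub))
    freqs[, k] <- rowSums(sub, na.rm = TRUE) / (2 * n_obs)
  }
  empty <- which(is.na(freqs) | !is.finite(freqs), arr.ind = TRUE)
  if (nrow(empty)) {
    cells <- paste0(rownames(counts)[empty[, 1]], "/", pops[empty[, 2]])
    abort(sprintf(
      "no non-missing genotypes for %d (marker, population) cell(s): %s%s",
      nrow(empty), toString(head(cells, 5)), if (nrow(empty) > 5) ", ..." else ""
    ))
  }
  al <- reference$alleles
  if (!is.null(al)) al <- al[match(rownames(counts), al$marker_id), ]
  founder_panel(freqs, alleles = al)
}

#' Restrict a panel to a subset of populations
#'
#' Used by under-specified (type-1) trials, where one truly contributing
#' population is deliberately left out of the design.
#'
#' @param panel a [founder_panel()].
#' @param keep character vector of population names to retain (also sets the
#'   column order).
#' @return A [founder_panel()] with the requested columns; markers unchanged.
#' @export
subset_panel <- function(panel, keep) {
  stopifnot(inherits(panel, "founder_panel"))
  if (!length(keep)) abort("`keep` must name at least one population.")
  unknown <- setdiff(keep, colnames(panel$freqs))
  if (length(unknown)) abort(sprintf("unknown population(s): %s", toString(unknown)))
  founder_panel(panel$freqs[, keep, drop = FALSE], alleles = panel$alleles)
}

#' Build the two-column design of a miss-specified (type-2) trial
#'
#' Column one is the focal population's expected allele content taken from
#' `panel`; column two is the expected allele content computed directly from
#' `n_sample` genotypes drawn uniformly without replacement from a pool of
#' non-focal reference genotypes. This models the situation where one
#' contributing founder is precisely specified but only a vague average is
#' known for everything else.
#'
#' @param panel a [founder_panel()] containing the focal population.
#' @param focal focal population name.
#' @param pool a [geno_matrix()] of candidate background genotypes; must not
#'   contain focal-population individuals (checked when `pool_labels` given).
#' @param pool_labels optional labels tibble for `pool`, used to verify the
#'   focal population is absent.
#' @param n_sample number of background genotypes to draw (default 500).
#' @param seed optional integer seed making the draw reproducible.
#' @return A two-column [founder_panel()] with columns `focal` and
#'   `"background"`.
#' @export
build_type2_design <- function(panel, focal, pool, pool_labels = NULL,
                               n_sample = 500, seed = NULL) {
  stopifnot(inherits(panel, "founder_panel"), inherits(pool, "geno_matrix"))
  if (!focal %in% colnames(panel$freqs)) {
    abort(sprintf("focal population '%s' not in panel.", focal))
  }
  if (!is.null(pool_labels)) {
    inpool <- pool_labels$individual_id[pool_labels$population == focal]
    if (any(inpool %in% individual_ids(pool))) {
      abort(sprintf("pool contains %d individual(s) of the focal population.",
                    sum(inpool %in% individual_ids(pool))))
    }
  }
  if (n_sample > ncol(pool$counts)) {
    abort(sprintf("n_sample (%d) exceeds pool size (%d).", n_sample, ncol(pool$counts)))
  }
  markers <- rownames(panel$freqs)
  missing_m <- setdiff(markers, marker_ids(pool))
  if (length(missing_m)) {
    abort(sprintf("pool lacks %d panel marker(s).", length(missing_m)))
  }
  draw <- function() sample(ncol(pool$counts), n_sample)
  idx <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  bg <- pool$counts[markers, idx, drop = FALSE]
  bg_freq <- rowMeans(bg, na.rm = TRUE) / 2
  f <- cbind(panel$freqs[, focal], bg_freq)
  dimnames(f) <- list(markers, c(focal, "background"))
  founder_panel(f, alleles = panel$alleles)
}

#' Correlations between panel frequency columns
#'
#' Pearson correlations between the populations' allele-frequency vectors —
#' a simple relatedness summary of the founder set (close relatives have
#' highly correlated frequency columns). Constant columns yield `NA` entries
#' with a warning.
#'
#' @param panel a [founder_panel()] with at least two populations.
#' @return An N-by-N correlation matrix.
#' @export
panel_correlations <- function(panel) {
  stopifnot(inherits(panel, "founder_panel"))
  if (ncol(panel$freqs) < 2) abort("need at least two populations.")
  sds <- apply(panel$freqs, 2, stats::sd)
  if (any(sds == 0)) {
    warn(sprintf("constant frequency column(s): %s; correlations reported as NA.",
                 toString(colnames(panel$freqs)[sds == 0])))
  }
  suppressWarnings(cor(panel$freqs))
}
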