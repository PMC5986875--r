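#' Genotype matrix of allele counts
#'
#' A `geno_matrix` stores bi-allelic genotypes as counts (0, 1, 2 or `NA`)
#' of one designated ("counted") allele per marker, as a markers-by-individuals
#' integer matrix. The counted allele is fixed per marker and recorded in the
#' `alleles` table, so two matrices genotyped against opposite strands or
#' allele orders can be reconciled with [align_markers()].
#'
#' @param counts integer matrix, markers in rows and individuals in columns,
#'   with `rownames` = marker ids and `colnames` = individual ids. Entries must
#'   be 0, 1, 2 or `NA`.
#' @param alleles optional tibble with columns `marker_id`, `counted`, `other`
#'   giving the identity of the counted allele (and its alternative) for each
#'   marker. May be `NULL` for formats that carry no allele labels.
#'
#' @return An object of class `geno_matrix`: a list with elements `counts`
#'   and `alleles`.
#' @export
geno_matrix <- function(counts, alleles = NULL) {
  if (!is.matrix(counts)) abort("`counts` must be a matrix.")
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    abort("`counts` must have marker ids as rownames and individual ids as colnames.")
  }
  if (anyDuplicated(rownames(counts))) abort("marker ids must be unique.")
  if (anyDuplicated(colnames(counts))) abort("individual ids must be unique.")
  storage.mode(counts) <- "integer"
  bad <- which(!is.na(counts) & !(counts %in% 0:2))
  if (length(bad)) {
    i <- arrayInd(bad[1], dim(counts))
    abort(sprintf(
      "genotype counts must be 0, 1, 2 or missing; found %s at marker '%s', individual '%s' (%d offending entries).",
      counts[bad[1]], rownames(counts)[i[1]], colnames(counts)[i[2]], length(bad)
    ))
  }
  if (!is.null(alleles)) {
    alleles <- as_tibble(alleles)
    need <- c("marker_id", "counted", "other")
    if (!all(need %in% names(alleles))) {
      abort("`alleles` must have columns marker_id, counted, other.")
    }
    alleles <- alleles[match(rownames(counts), alleles$marker_id), need]
    if (anyNA(alleles$marker_id)) abort("`alleles` must cover every marker in `counts`.")
  }
  structure(list(counts = counts, alleles = alleles), class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf(
    "<geno_matrix> %d markers x %d individuals (%s allele labels, %.1f%% missing)\n",
    nrow(x$counts), ncol(x$counts),
    if (is.null(x$alleles)) "no" else "with",
    100 * mean(is.na(x$counts))
  ))
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$counts)

#' Marker and individual ids of a genotype matrix
#' @param x a [geno_matrix()].
#' @return Character vector of ids.
#' @export
marker_ids <- function(x) rownames(x$counts)

#' @rdname marker_ids
#' @export
individual_ids <- function(x) colnames(x$counts)

#' @describeIn geno_matrix long-format view: one row per
#'   (marker, individual) cell with its allele count.
#' @param x a `geno_matrix`.
#' @param ... unused.
#' @method as_tibble geno_matrix
#' @export
as_tibble.geno_matrix <- function(x, ...) {
  tibble(
    marker_id = rep(rownames(x$counts), times = ncol(x$counts)),
    individual_id = rep(colnames(x$counts), each = nrow(x$counts)),
    count = as.integer(x$counts)
  )
}

#' Subset a genotype matrix by marker and/or individual ids
#'
#' Keeps the requested ids in the given order; allele labels follow.
#' @param x a [geno_matrix()].
#' @param markers,individuals character vectors of ids to keep (`NULL` keeps
#'   all).
#' @return A [geno_matrix()].
#' @export
subset_geno <- function(x, markers = NULL, individuals = NULL) {
  counts <- x$counts
  if (!is.null(markers)) {
    miss <- setdiff(markers, rownames(counts))
    if (length(miss)) abort(sprintf("unknown marker ids: %s", toString(head(miss, 5))))
    counts <- counts[markers, , drop = FALSE]
  }
  if (!is.null(individuals)) {
    miss <- setdiff(individuals, colnames(counts))
    if (length(miss)) abort(sprintf("unknown individual ids: %s", toString(head(miss, 5))))
    counts <- counts[, individuals, drop = FALSE]
  }
  alleles <- x$alleles
  if (!is.null(alleles)) alleles <- alleles[match(rownames(counts), alleles$marker_id), ]
  geno_matrix(counts, alleles)
}

#' Harmonise two genotype matrices to a shared marker set
#'
#' Restricts `target` and `reference` to their common markers (in reference
#' order) and harmonises the counted allele: where the two matrices counted
#' opposite alleles of the same pair, target counts are flipped to `2 - count`.
#' Markers whose allele pairs cannot be reconciled (e.g. different allele
#' letters entirely) are dropped, and the number dropped is reported via a
#' message and the `"n_dropped"` attribute of the result.
#'
#' @param target,reference [geno_matrix()] objects carrying allele labels.
#' @return A list with elements `target` and `reference`, both restricted to
#'   the reconciled common markers, target counts expressed on the reference's
#'   counted allele.
#' @export
align_markers <- function(target, reference) {
  stopifnot(inherits(target, "geno_matrix"), inherits(reference, "geno_matrix"))
  if (is.null(target$alleles) || is.null(reference$alleles)) {
    abort("both matrices must carry allele labels to be aligned.")
  }
  common <- intersect(marker_ids(reference), marker_ids(target))
  if (!length(common)) abort("no markers in common between target and reference.")
  ta <- target$alleles[match(common, target$alleles$marker_id), ]
  ra <- reference$alleles[match(common, reference$alleles$marker_id), ]
  same <- ta$counted == ra$counted & ta$other == ra$other
  swapped <- ta$counted == ra$other & ta$other == ra$counted
  keep <- common[same | swapped]
  n_dropped <- length(common) - length(keep)
  if (!length(keep)) abort("no markers with reconcilable alleles.")
  if (n_dropped > 0) {
    inform(sprintf("align_markers: dropped %d marker(s) with irreconcilable alleles.", n_dropped))
  }
  tc <- target$counts[keep, , drop = FALSE]
  flip <- swapped[match(keep, common)]
  tc[flip, ] <- 2L - tc[flip, , drop = FALSE]
  out_t <- geno_matrix(tc, ra[match(keep, ra$marker_id), ])
  out_r <- subset_geno(reference, markers = keep)
  structure(list(target = out_t, reference = out_r), n_dropped = n_dropped)
}
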