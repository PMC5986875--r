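#' Read genotypes into a genotype matrix
#'
#' Reads bi-allelic genotypes from one of three dialects and returns counts of
#' a designated allele per marker:
#'
#' * `"tsv"`: tab-separated matrix, rows = markers, columns = individuals,
#'   first column the marker id, entries 0/1/2 or `NA`; `#` lines are comments.
#'   No allele labels are carried.
#' * `"vcf"`: VCF v4.x with a `GT` field; the count is the dosage of the ALT
#'   allele. Multi-allelic records are rejected.
#' * `"plink"`: PLINK text `.ped`/`.map` pair (`path` may be either file or the
#'   common prefix). The counted allele is the minor allele over the file
#'   (ties broken alphabetically); `0` alleles are missing.
#'
#' @param path path to the file (or PLINK prefix).
#' @param format one of `"tsv"`, `"vcf"`, `"plink"`.
#' @return A [geno_matrix()].
#' @export
read_genotypes <- function(path, format = c("tsv", "vcf", "plink")) {
  format <- match.arg(format)
  switch(format,
    tsv = read_genotypes_tsv(path),
    vcf = read_genotypes_vcf(path),
    plink = read_genotypes_plink(path)
  )
}

read_genotypes_tsv <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  df <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                        col_types = readr::cols(.default = readr::col_character()))
  if (ncol(df) < 2) abort(sprintf("parse error in %s: need a marker id column plus >=1 individual.", path))
  ids <- df[[1]]
  m <- as.matrix(df[-1])
  bad <- which(!is.na(m) & !(m %in% c("0", "1", "2", "NA", "")))
  if (length(bad)) {
    i <- arrayInd(bad[1], dim(m))
    abort(sprintf(
      "invalid genotype '%s' at line %d (marker '%s', individual '%s') in %s; counts must be 0, 1 or 2.",
      m[bad[1]], i[1] + 1L, ids[i[1]], colnames(m)[i[2]], path
    ))
  }
  m[m %in% c("NA", "")] <- NA
  storage.mode(m) <- "integer"
  rownames(m) <- ids
  geno_matrix(m)
}

read_genotypes_vcf <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  fix <- matrix(fix, ncol = 7, dimnames = list(NULL, c("CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER")))
  ids <- fix[, "ID"]
  noid <- is.na(ids) | ids == "."
  ids[noid] <- paste0(fix[noid, "CHROM"], ":", fix[noid, "POS"])
  multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
  if (any(multi)) {
    abort(sprintf("multi-allelic marker(s) not supported: %s", toString(head(ids[multi], 5))))
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  # dosage of the ALT allele; any missing allele call -> NA
  dose <- function(g) {
    a <- strsplit(g, "[/|]")
    vapply(a, function(z) {
      if (length(z) != 2 || any(z == ".") || any(is.na(z))) return(NA_integer_)
      sum(z == "1")
    }, integer(1))
  }
  m <- apply(gt, 2, dose)
  if (is.null(dim(m))) m <- matrix(m, nrow = nrow(gt), dimnames = dimnames(gt))
  rownames(m) <- ids
  geno_matrix(m, alleles = tibble(marker_id = ids, counted = fix[, "ALT"], other = fix[, "REF"]))
}

read_genotypes_plink <- function(path) {
  prefix <- sub("\\.(ped|map)$", "", path)
  ped <- paste0(prefix, ".ped"); map <- paste0(prefix, ".map")
  if (!file.exists(ped) || !file.exists(map)) {
    abort(sprintf("need both %s and %s.", ped, map))
  }
  mp <- utils::read.table(map, header = FALSE, stringsAsFactors = FALSE, comment.char = "#")
  mids <- as.character(mp[[2]])
  pd <- utils::read.table(ped, header = FALSE, stringsAsFactors = FALSE, comment.char = "#",
                          colClasses = "character")
  if (ncol(pd) != 6 + 2 * length(mids)) {
    abort(sprintf("parse error in %s: %d columns, expected %d (6 + 2 x %d markers).",
                  ped, ncol(pd), 6 + 2 * length(mids), length(mids)))
  }
  iids <- pd[[2]]
  M <- length(mids); L <- nrow(pd)
  counts <- matrix(NA_integer_, M, L, dimnames = list(mids, iids))
  counted <- other <- character(M)
  for (i in seq_len(M)) {
    a1 <- pd[[6 + 2 * i - 1]]; a2 <- pd[[6 + 2 * i]]
    miss <- a1 == "0" | a2 == "0"
    obs <- c(a1[!miss], a2[!miss])
    al <- sort(unique(obs))
    if (length(al) > 2) {
      abort(sprintf("multi-allelic marker '%s' in %s: alleles %s.", mids[i], ped, toString(al)))
    }
    if (length(al) == 0) { counted[i] <- other[i] <- NA_character_; next }
    if (length(al) == 1) al <- c(al, NA_character_)
    # counted allele = minor (lower count; tie -> alphabetical first)
    n1 <- sum(obs == al[1]); n2 <- sum(obs == al[2])
    if (!is.na(al[2]) && n2 < n1) al <- al[2:1]
    counted[i] <- al[1]; other[i] <- al[2]
    counts[i, !miss] <- (a1[!miss] == al[1]) + (a2[!miss] == al[1])
  }
  geno_matrix(counts, alleles = tibble(marker_id = mids, counted = counted, other = other))
}

#' Write a genotype matrix as TSV
#'
#' Inverse of `read_genotypes(format = "tsv")`; allele labels are not written.
#' @param x a [geno_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(x, path) {
  stopifnot(inherits(x, "geno_matrix"))
  df <- as.data.frame(x$counts)
  df <- cbind(marker_id = rownames(x$counts), df)
  readr::write_tsv(tibble::as_tibble(df), path, na = "NA")
  invisible(path)
}

#' Read an individual-to-population labels file
#'
#' Two tab-separated columns: individual id and population name (`#` comments
#' allowed; a header line is optional and detected by the column names
#' `individual_id`/`population`).
#'
#' @param path path to the labels TSV.
#' @return A tibble with columns `individual_id` and `population`.
#' @export
read_labels <- function(path) {
  first <- readLines(path, n = 50)
  first <- first[!startsWith(first, "#")][1]
  has_header <- grepl("individual_id", first, fixed = TRUE)
  df <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                        col_names = if (has_header) TRUE else c("individual_id", "population"),
                        col_types = readr::cols(.default = readr::col_character()))
  tibble(individual_id = df[[1]], population = df[[2]])
}

#' @rdname read_labels
#' @param labels tibble with columns `individual_id`, `population`.
#' @export
write_labels <- function(labels, path) {
  readr::write_tsv(labels[c("individual_id", "population")], path)
  invisible(path)
}

# --- proportion / truth tables -------------------------------------------

prop_populations <- function(x) {
  setdiff(names(x), c("individual_id", grep("^\\.", names(x), value = TRUE)))
}

#' Write estimated (or true) genome proportions as TSV
#'
#' Rows are individuals, columns the founder populations, values printed with
#' six decimal places; diagnostic columns (names starting with `.`) are
#' dropped. A list of proportion tables may be given; they are stacked after
#' checking that all share one population order.
#'
#' @param x a wide proportions tibble (`individual_id` + one column per
#'   population), a [cgr_estimate()] fit, or a list of either.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_proportions <- function(x, path) {
  tabs <- if (inherits(x, "cgr_fit")) list(x$proportions)
          else if (is.data.frame(x)) list(x)
          else lapply(x, function(e) if (inherits(e, "cgr_fit")) e$proportions else e)
  pops <- lapply(tabs, prop_populations)
  if (length(tabs) > 1 && !all(vapply(pops[-1], identical, logical(1), pops[[1]]))) {
    abort("all proportion tables must share one population order.")
  }
  tab <- dplyr::bind_rows(lapply(tabs, function(t) t[c("individual_id", pops[[1]])]))
  tab <- dplyr::mutate(tab, dplyr::across(-"individual_id", ~ sprintf("%.6f", .x)))
  readr::write_tsv(tab, path)
  invisible(path)
}

#' @rdname write_proportions
#' @export
read_proportions <- function(path) {
  df <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  df[[1]] <- as.character(df[[1]])
  names(df)[1] <- "individual_id"
  as_tibble(df)
}

#' Read or write a founder allele-frequency table
#'
#' TSV with rows = markers (first column `marker_id`) and one column of
#' frequencies per population. `read_frequencies()` returns a
#' [founder_panel()].
#'
#' @param path file path.
#' @return `read_frequencies()`: a [founder_panel()]; `write_frequencies()`:
#'   `path` invisibly.
#' @export
read_frequencies <- function(path) {
  df <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  f <- as.matrix(df[-1])
  rownames(f) <- as.character(df[[1]])
  founder_panel(f)
}

#' @rdname read_frequencies
#' @param panel a [founder_panel()].
#' @export
write_frequencies <- function(panel, path) {
  stopifnot(inherits(panel, "founder_panel"))
  df <- as.data.frame(panel$freqs)
  df <- cbind(marker_id = rownames(panel$freqs), df)
  df[-1] <- lapply(df[-1], function(z) sprintf("%.8f", z))
  readr::write_tsv(tibble::as_tibble(df), path)
  invisible(path)
}
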