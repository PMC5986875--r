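#' Randomly phase a genotype into two haplotypes
#'
#' Homozygous markers split deterministically (0 into 0|0, 2 into 1|1);
#' at heterozygous markers the counted allele is assigned to haplotype one or
#' two with probability 1/2 independently per marker. Both origin vectors are
#' set to the individual's own population, so founders start with fully
#' labelled chromosomes.
#'
#' @param genotype integer vector of allele counts (0/1/2, no missing — impute
#'   first, see [breed()]).
#' @param population integer index of the individual's founder population.
#' @return A list with `hap1`, `hap2` (0/1 vectors summing to `genotype`) and
#'   `origin1`, `origin2` (constant `population`).
#' @export
random_phase <- function(genotype, population = 1L) {
  if (anyNA(genotype)) abort("genotype contains missing values; impute before phasing.")
  if (!all(genotype %in% 0:2)) abort("genotype counts must be 0, 1 or 2.")
  M <- length(genotype)
  het <- genotype == 1L
  toss <- stats::runif(M) < 0.5
  hap1 <- as.integer(genotype == 2L | (het & toss))
  hap2 <- as.integer(genotype == 2L | (het & !toss))
  list(hap1 = hap1, hap2 = hap2,
       origin1 = rep(as.integer(population), M),
       origin2 = rep(as.integer(population), M))
}

#' Form a gamete by recombining a parent's haplotypes
#'
#' Draws exactly `n_crossovers` breakpoints uniformly without replacement from
#' the M-1 inter-marker intervals of the concatenated marker sequence, starts
#' copying from either parental haplotype with probability 1/2, and switches
#' source at every breakpoint. Founder-origin labels travel with the alleles,
#' which is what makes exact ancestry truth available downstream.
#'
#' @param parent a haplotype pair as returned by [random_phase()] (or an
#'   offspring's pair from [breed()]).
#' @param n_crossovers fixed number of crossovers per gamete (not Poisson).
#' @return A list with `hap` and `origin`, each length M.
#' @export
make_gamete <- function(parent, n_crossovers) {
  M <- length(parent$hap1)
  if (n_crossovers < 0) abort("n_crossovers must be >= 0.")
  if (n_crossovers > M - 1) {
    abort(sprintf("n_crossovers (%d) exceeds the %d inter-marker intervals.", n_crossovers, M - 1))
  }
  start <- sample(2L, 1L)
  sw <- integer(M)
  if (n_crossovers > 0) {
    bp <- sample.int(M - 1L, n_crossovers)
    sw[bp + 1L] <- 1L
  }
  src <- (start - 1L + cumsum(sw)) %% 2L + 1L   # 1 or 2 per marker
  from1 <- src == 1L
  list(
    hap = ifelse(from1, parent$hap1, parent$hap2),
    origin = ifelse(from1, parent$origin1, parent$origin2)
  )
}

#' True founder proportions from origin labels
#'
#' @param origin1,origin2 integer vectors of founder-population indices for
#'   the two haplotypes.
#' @param n_pops number of founder populations (defaults to the largest label).
#' @param populations optional character names for the populations.
#' @return A numeric vector of proportions summing to exactly 1 (rationals
#'   with denominator 2M).
#' @export
true_proportions <- function(origin1, origin2, n_pops = max(origin1, origin2),
                             populations = NULL) {
  stopifnot(length(origin1) == length(origin2))
  M <- length(origin1)
  b <- tabulate(c(origin1, origin2), nbins = n_pops) / (2 * M)
  if (!is.null(populations)) names(b) <- populations
  b
}

#' Breeding scheme for the admixture simulator
#'
#' Describes a multi-generation random-mating design: in each generation g,
#' `n_pairs[g]` sire/dam pairs are drawn with replacement from the previous
#' generation's offspring (generation 1 draws from the founders), respecting
#' randomly assigned sexes, and each pair produces one offspring from two
#' recombinant gametes. All generations' offspring form the admixed set.
#'
#' @param n_pairs integer vector, matings (= offspring) per generation.
#' @param n_crossovers crossovers per gamete.
#' @param seed optional integer seed; fixing it makes [breed()] fully
#'   reproducible.
#' @return A `breeding_scheme` object.
#' @export
breeding_scheme <- function(n_pairs, n_crossovers = 25, seed = NULL) {
  if (!length(n_pairs) || any(n_pairs < 1)) abort("all per-generation pair counts must be >= 1.")
  if (n_crossovers < 0) abort("n_crossovers must be >= 0.")
  structure(list(n_pairs = as.integer(n_pairs),
                 n_crossovers = as.integer(n_crossovers),
                 seed = seed),
            class = "breeding_scheme")
}

#' @describeIn breeding_scheme cattle-style design: `n_generations` rounds of
#'   `n_pairs` matings each (defaults 5 x 1000, i.e. 5,000 admixed).
#' @param n_generations number of rounds.
#' @export
scheme_cattle <- function(n_pairs = 1000, n_generations = 5, n_crossovers = 25, seed = NULL) {
  breeding_scheme(rep(n_pairs, n_generations), n_crossovers, seed)
}

#' @describeIn breeding_scheme human-style design: five generations F1-F5
#'   totalling 1,000 offspring with per-parent progeny expectation rising from
#'   about one to two (100, 150, 200, 250, 300).
#' @export
scheme_human <- function(n_crossovers = 25, seed = NULL) {
  breeding_scheme(c(100, 150, 200, 250, 300), n_crossovers, seed)
}

#' @export
print.breeding_scheme <- function(x, ...) {
  cat(sprintf("<breeding_scheme> %d generation(s), pairs per generation: %s; %d crossovers/gamete%s\n",
              length(x$n_pairs), toString(x$n_pairs), x$n_crossovers,
              if (is.null(x$seed)) "" else sprintf("; seed %d", x$seed)))
  invisible(x)
}

#' Simulate artificially admixed individuals from founder genotypes
#'
#' Founder genotypes are randomly phased into haplotypes (missing genotypes
#' first imputed by a Hardy-Weinberg draw from their population's allele
#' frequency), then bred through the scheme's generations: random sexes,
#' parents drawn with replacement, one offspring per pair formed by uniting
#' two gametes made with a fixed number of uniformly placed crossovers.
#' Founder-origin labels are carried along every chromosome segment, so each
#' offspring's true genome proportions are exact marker counts, not
#' pedigree expectations.
#'
#' @param founders a [geno_matrix()] of founder individuals.
#' @param labels tibble (`individual_id`, `population`) covering all founders;
#'   population order in the truth table follows first appearance.
#' @param scheme a [breeding_scheme()].
#' @return A list with
#'   \describe{
#'     \item{genotypes}{[geno_matrix()] of all offspring (ids
#'       `adm_g<generation>_<index>`).}
#'     \item{truth}{wide tibble of exact true proportions: `individual_id`,
#'       one column per founder population, plus `.generation`.}
#'     \item{populations}{founder population order.}
#'   }
#' @export
breed <- function(founders, labels, scheme) {
  stopifnot(inherits(founders, "geno_matrix"), inherits(scheme, "breeding_scheme"))
  run <- function() .breed_impl(founders, labels, scheme)
  if (is.null(scheme$seed)) run() else withr::with_seed(scheme$seed, run())
}

.breed_impl <- function(founders, labels, scheme) {
  miss <- setdiff(individual_ids(founders), labels$individual_id)
  if (length(miss)) {
    abort(sprintf("unlabelled founder(s): %s", toString(head(miss, 5))))
  }
  pops <- unique(labels$population)
  pop_idx <- match(labels$population[match(individual_ids(founders), labels$individual_id)], pops)
  counts <- founders$counts
  M <- nrow(counts)
  if (scheme$n_crossovers > M - 1) {
    abort(sprintf("n_crossovers (%d) exceeds the %d inter-marker intervals.",
                  scheme$n_crossovers, M - 1))
  }

  # impute missing founder genotypes from their population frequency (HWE)
  if (anyNA(counts)) {
    pf <- vapply(seq_along(pops), function(k) {
      sub <- counts[, pop_idx == k, drop = FALSE]
      rowSums(sub, na.rm = TRUE) / (2 * pmax(rowSums(!is.na(sub)), 1))
    }, numeric(M))
    na_cells <- which(is.na(counts), arr.ind = TRUE)
    counts[na_cells] <- rbinom(nrow(na_cells), 2, pf[cbind(na_cells[, 1], pop_idx[na_cells[, 2]])])
  }

  # phase all founders (vectorised over the matrix)
  nf <- ncol(counts)
  het <- counts == 1L
  toss <- matrix(stats::runif(M * nf) < 0.5, M, nf)
  hap1 <- (counts == 2L) | (het & toss)
  hap2 <- (counts == 2L) | (het & !toss)
  storage.mode(hap1) <- storage.mode(hap2) <- "integer"
  or_const <- pop_idx  # founder origins are constant per column

  pool <- list(
    hap1 = hap1, hap2 = hap2,
    or1 = matrix(rep(or_const, each = M), M, nf),
    or2 = matrix(rep(or_const, each = M), M, nf)
  )

  all_counts <- vector("list", length(scheme$n_pairs))
  all_truth <- vector("list", length(scheme$n_pairs))
  n_pops <- length(pops)

  for (g in seq_along(scheme$n_pairs)) {
    n_off <- scheme$n_pairs[g]
    n_parents <- ncol(pool$hap1)
    sex <- sample(c(TRUE, FALSE), n_parents, replace = TRUE)  # TRUE = male
    males <- which(sex); females <- which(!sex)
    if (!length(males) || !length(females)) {
      abort(sprintf("generation %d: no %s available to serve as parents.",
                    g, if (!length(males)) "males" else "females"))
    }
    sires <- males[sample.int(length(males), n_off, replace = TRUE)]
    dams <- females[sample.int(length(females), n_off, replace = TRUE)]

    o_h1 <- o_h2 <- o_o1 <- o_o2 <- matrix(0L, M, n_off)
    for (i in seq_len(n_off)) {
      gs <- make_gamete(list(hap1 = pool$hap1[, sires[i]], hap2 = pool$hap2[, sires[i]],
                             origin1 = pool$or1[, sires[i]], origin2 = pool$or2[, sires[i]]),
                        scheme$n_crossovers)
      gd <- make_gamete(list(hap1 = pool$hap1[, dams[i]], hap2 = pool$hap2[, dams[i]],
                             origin1 = pool$or1[, dams[i]], origin2 = pool$or2[, dams[i]]),
                        scheme$n_crossovers)
      o_h1[, i] <- gs$hap; o_o1[, i] <- gs$origin
      o_h2[, i] <- gd$hap; o_o2[, i] <- gd$origin
    }
    ids <- sprintf("adm_g%d_%d", g, seq_len(n_off))
    colnames(o_h1) <- colnames(o_h2) <- ids
    cnt <- o_h1 + o_h2
    dimnames(cnt) <- list(rownames(counts), ids)
    all_counts[[g]] <- cnt
    tr <- vapply(seq_len(n_off),
                 function(i) true_proportions(o_o1[, i], o_o2[, i], n_pops),
                 numeric(n_pops))
    tr <- matrix(tr, nrow = n_off, ncol = n_pops, byrow = TRUE,
                 dimnames = list(NULL, pops))
    all_truth[[g]] <- dplyr::bind_cols(
      tibble(individual_id = ids),
      as_tibble(as.data.frame(tr)),
      tibble(.generation = g)
    )
    pool <- list(hap1 = o_h1, hap2 = o_h2, or1 = o_o1, or2 = o_o2)
  }

  geno <- geno_matrix(do.call(cbind, all_counts), alleles = founders$alleles)
  list(genotypes = geno,
       truth = dplyr::bind_rows(all_truth),
       populations = pops)
}

#' Simulate differentiated founder populations
#'
#' Generates reference genotypes for `n_pops` founder populations under the
#' Balding-Nichols model: ancestral frequencies are uniform on
#' `[0.05, 0.95]`, each population's frequency is a Beta draw around the
#' ancestral value with differentiation `fst`, and genotypes are binomial
#' (2 trials) under Hardy-Weinberg. Optionally the last population is made a
#' close relative of an existing one by re-drawing its frequencies around
#' that population's (differentiation `sister_fst`), which plants a pair of
#' highly correlated frequency columns — useful for studying what happens
#' when a panel population has a near relative.
#'
#' @param n_pops number of founder populations.
#' @param n_markers number of bi-allelic markers.
#' @param n_per_pop reference individuals per population.
#' @param fst differentiation of each population from the common ancestor,
#'   in (0, 1).
#' @param seed optional integer seed.
#' @param sister_of optional population index; the last population's
#'   frequencies are then drawn around population `sister_of`'s.
#' @param sister_fst differentiation of the planted relative (default 0.05).
#' @return A list with `genotypes` ([geno_matrix()]; synthetic allele labels
#'   `"A"`/`"B"`), `labels` (tibble), and `freqs` (the true M-by-N frequency
#'   matrix the genotypes were drawn from).
#' @export
make_synthetic_founders <- function(n_pops, n_markers, n_per_pop, fst,
                                    seed = NULL, sister_of = NULL,
                                    sister_fst = 0.05) {
  if (fst <= 0 || fst >= 1) abort("`fst` must lie in (0, 1).")
  if (n_pops < 1 || n_markers < 1 || n_per_pop < 1) abort("counts must be >= 1.")
  if (!is.null(sister_of) && (sister_of < 1 || sister_of >= n_pops)) {
    abort("`sister_of` must index a population other than the last.")
  }
  run <- function() {
    p_anc <- runif(n_markers, 0.05, 0.95)
    bn <- function(p, f) {
      a <- p * (1 - f) / f
      b <- (1 - p) * (1 - f) / f
      pmin(pmax(rbeta(length(p), a, b), 1e-6), 1 - 1e-6)
    }
    pops <- paste0("pop", seq_len(n_pops))
    freqs <- vapply(seq_len(n_pops), function(k) bn(p_anc, fst), numeric(n_markers))
    dimnames(freqs) <- list(paste0("m", seq_len(n_markers)), pops)
    if (!is.null(sister_of)) {
      freqs[, n_pops] <- bn(freqs[, sister_of], sister_fst)
    }
    L <- n_pops * n_per_pop
    counts <- matrix(NA_integer_, n_markers, L)
    for (k in seq_len(n_pops)) {
      cols <- (k - 1) * n_per_pop + seq_len(n_per_pop)
      counts[, cols] <- rbinom(n_markers * n_per_pop, 2, freqs[, k])
    }
    ids <- paste0("ref_", rep(pops, each = n_per_pop), "_", rep(seq_len(n_per_pop), n_pops))
    dimnames(counts) <- list(rownames(freqs), ids)
    alleles <- tibble(marker_id = rownames(freqs), counted = "A", other = "B")
    list(
      genotypes = geno_matrix(counts, alleles),
      labels = tibble(individual_id = ids, population = rep(pops, each = n_per_pop)),
      freqs = freqs
    )
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}
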