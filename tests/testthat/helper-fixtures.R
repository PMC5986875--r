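# Shared fixtures, built in code at test time.

# tiny deterministic genotype matrix: 2 markers x 3 individuals
tiny_geno <- function() {
  m <- matrix(c(0L, 1L, 2L,
                2L, 1L, 0L), nrow = 2, byrow = TRUE,
              dimnames = list(c("m1", "m2"), c("i1", "i2", "i3")))
  geno_matrix(m, alleles = tibble::tibble(marker_id = c("m1", "m2"),
                                          counted = c("A", "C"),
                                          other = c("G", "T")))
}

# small two-population founder set with strongly separated frequencies,
# handy for noise-free-ish recovery checks
small_founders <- function(n_markers = 200, n_per_pop = 40, seed = 5) {
  make_synthetic_founders(2, n_markers, n_per_pop, fst = 0.3, seed = seed)
}

# random full-column-rank design with allele-content-scaled entries
random_design <- function(M, N) {
  matrix(runif(M * N, 0, 2), M, N, dimnames = list(NULL, paste0("p", seq_len(N))))
}

random_simplex <- function(N) {
  b <- rexp(N)
  b / sum(b)
}

# The study cohort used by the end-to-end evaluation tests: 8 founder
# populations (the last a close relative of pop7), 4,000 markers, 100
# reference individuals per population, differentiation 0.1; cattle-style
# random mating, 200 pairs x 5 rounds at 25 crossovers per gamete.
# Built once per test run and reused across the evaluation tests.
.cohort_env <- new.env(parent = emptyenv())

study_cohort <- function() {
  if (!is.null(.cohort_env$cohort)) return(.cohort_env$cohort)
  fd <- make_synthetic_founders(8, 4000, 100, fst = 0.1, seed = 101, sister_of = 7)
  panel <- estimate_frequencies(fd$genotypes, fd$labels)
  coh <- breed(fd$genotypes, fd$labels,
               scheme_cattle(n_pairs = 200, n_generations = 5,
                             n_crossovers = 25, seed = 202))
  .cohort_env$cohort <- list(founders = fd, panel = panel,
                             genotypes = coh$genotypes, truth = coh$truth)
  .cohort_env$cohort
}
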