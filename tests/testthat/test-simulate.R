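test_that("random phasing conserves the genotype and splits homozygotes deterministically", {
  set.seed(2)
  geno <- sample(0:2, 500, replace = TRUE)
  hp <- random_phase(geno, population = 3L)
  expect_identical(hp$hap1 + hp$hap2, geno)
  expect_true(all(hp$hap1[geno == 2] == 1), all(hp$hap2[geno == 2] == 1))
  expect_true(all(hp$hap1[geno == 0] == 0), all(hp$hap2[geno == 0] == 0))
  expect_true(all(hp$origin1 == 3L), all(hp$origin2 == 3L))

  hp2 <- random_phase(rep(2L, 10))
  expect_identical(hp2$hap1, rep(1L, 10))
  expect_identical(hp2$hap2, rep(1L, 10))

  expect_error(random_phase(c(0L, NA, 1L)), "missing")
})

test_that("heterozygote allele assignment is a fair coin over many sites", {
  set.seed(12)
  geno <- rep(1L, 10000)
  hp <- random_phase(geno)
  expect_lt(abs(mean(hp$hap1) - 0.5), 0.02)
})

test_that("gametes alternate source at exactly the drawn breakpoints", {
  M <- 100
  parent <- list(hap1 = rep(0L, M), hap2 = rep(1L, M),
                 origin1 = rep(1L, M), origin2 = rep(2L, M))
  set.seed(5)
  # zero crossovers: gamete equals one parental haplotype in full
  g0 <- make_gamete(parent, 0)
  expect_true(all(g0$hap == 0L) || all(g0$hap == 1L))
  expect_true(all(g0$origin == g0$hap + 1L))

  # one crossover: t markers of one origin then M - t of the other
  g1 <- make_gamete(parent, 1)
  runs <- rle(g1$origin)
  expect_length(runs$lengths, 2)
  expect_setequal(runs$values, c(1L, 2L))

  expect_error(make_gamete(parent, M), "inter-marker")
  expect_error(make_gamete(parent, -1), ">= 0")
})

test_that("starting haplotype is fair over many gametes", {
  M <- 20
  parent <- list(hap1 = rep(0L, M), hap2 = rep(1L, M),
                 origin1 = rep(1L, M), origin2 = rep(2L, M))
  set.seed(8)
  frac1 <- mean(vapply(1:10000, function(i) mean(make_gamete(parent, 3)$hap == 0L), numeric(1)))
  expect_lt(abs(frac1 - 0.5), 0.02)
})

test_that("true proportions are exact marker counts over both haplotypes", {
  expect_equal(true_proportions(rep(3L, 10), rep(3L, 10), n_pops = 4),
               c(0, 0, 1, 0))
  o1 <- c(rep(1L, 5), rep(2L, 5)); o2 <- rep(1L, 10)
  expect_equal(true_proportions(o1, o2, n_pops = 2), c(0.75, 0.25))
  set.seed(3)
  for (i in 1:20) {
    oa <- sample(1:4, 37, replace = TRUE)
    ob <- sample(1:4, 37, replace = TRUE)
    expect_equal(sum(true_proportions(oa, ob, n_pops = 4)), 1)
  }
})

test_that("F1 crosses have exact half-and-half ancestry; purebred matings stay pure", {
  # two founders, one of each population, forced into one mating pair
  counts <- matrix(c(rep(0L, 50), rep(2L, 50)), ncol = 2,
                   dimnames = list(paste0("m", 1:50), c("fA", "fB")))
  g <- geno_matrix(counts)
  lab <- tibble::tibble(individual_id = c("fA", "fB"), population = c("A", "B"))
  found <- FALSE
  for (seed in 1:20) {
    coh <- try(breed(g, lab, breeding_scheme(1, n_crossovers = 2, seed = seed)), silent = TRUE)
    if (inherits(coh, "try-error")) next  # both founders drew the same sex
    found <- TRUE
    expect_equal(coh$truth$A, 0.5)
    expect_equal(coh$truth$B, 0.5)
    break
  }
  expect_true(found)

  # both parents from one population: offspring is fully that population
  counts2 <- matrix(sample(0:2, 200, replace = TRUE), 50, 4,
                    dimnames = list(paste0("m", 1:50), paste0("f", 1:4)))
  g2 <- geno_matrix(counts2)
  lab2 <- tibble::tibble(individual_id = paste0("f", 1:4), population = "A")
  coh2 <- breed(g2, lab2, breeding_scheme(5, n_crossovers = 3, seed = 4))
  expect_true(all(coh2$truth$A == 1))
})

test_that("breeding is bit-for-bit reproducible under a fixed seed", {
  fd <- small_founders(n_markers = 100, n_per_pop = 10)
  sc <- breeding_scheme(c(8, 8), n_crossovers = 5, seed = 77)
  a <- breed(fd$genotypes, fd$labels, sc)
  b <- breed(fd$genotypes, fd$labels, sc)
  expect_identical(a$genotypes$counts, b$genotypes$counts)
  expect_identical(a$truth, b$truth)
})

test_that("offspring ancestry equals the parental mean in expectation", {
  # one A x B founder pair -> every F1 is exactly (0.5, 0.5); 1,000 F2
  # matings among those F1s must then average 0.5 per population
  counts <- matrix(c(rep(0L, 300), rep(2L, 300)), ncol = 2,
                   dimnames = list(paste0("m", 1:300), c("fA", "fB")))
  g <- geno_matrix(counts)
  lab <- tibble::tibble(individual_id = c("fA", "fB"), population = c("A", "B"))
  coh <- NULL
  for (seed in 1:30) {
    coh <- try(breed(g, lab, breeding_scheme(c(200, 1000), n_crossovers = 5, seed = seed)),
               silent = TRUE)
    if (!inherits(coh, "try-error")) break
  }
  f1 <- coh$truth[coh$truth$.generation == 1, ]
  expect_true(all(f1$A == 0.5))
  f2 <- coh$truth[coh$truth$.generation == 2, ]
  expect_lt(abs(mean(f2$A) - 0.5), 0.02)
  expect_gt(stats::sd(f2$A), 0)  # crossovers do create variation around the mean
})

test_that("unlabelled founders and impossible crossover counts are errors", {
  fd <- small_founders(n_markers = 50, n_per_pop = 5)
  expect_error(breed(fd$genotypes, fd$labels[-1, ], breeding_scheme(2, 1, seed = 1)),
               "unlabelled")
  expect_error(breed(fd$genotypes, fd$labels, breeding_scheme(2, 50, seed = 1)),
               "inter-marker")
  expect_error(breeding_scheme(0, 5), ">= 1")
})

test_that("missing founder genotypes are imputed before phasing", {
  fd <- small_founders(n_markers = 60, n_per_pop = 10)
  fd$genotypes$counts[1, 1] <- NA
  fd$genotypes$counts[10, 3] <- NA
  coh <- breed(fd$genotypes, fd$labels, breeding_scheme(5, 3, seed = 2))
  expect_false(anyNA(coh$genotypes$counts))
})

test_that("synthetic founders follow the requested differentiation model", {
  # fst -> 0: population frequencies converge to the ancestral frequency
  fd0 <- make_synthetic_founders(3, 1000, 2, fst = 1e-4, seed = 9)
  spread <- apply(fd0$freqs, 1, function(z) diff(range(z)))
  expect_lt(max(spread), 0.05)

  # genotype means match 2p within binomial error
  fd <- make_synthetic_founders(2, 800, 200, fst = 0.2, seed = 10)
  panel <- estimate_frequencies(fd$genotypes, fd$labels)
  se <- sqrt(fd$freqs * (1 - fd$freqs) / (2 * 200))
  expect_gt(mean(abs(panel$freqs - fd$freqs) <= 4 * se), 0.999)

  fd1 <- make_synthetic_founders(1, 10, 5, fst = 0.1, seed = 1)
  expect_equal(unique(fd1$labels$population), "pop1")

  expect_error(make_synthetic_founders(2, 10, 5, fst = 0), "fst")
  expect_error(make_synthetic_founders(2, 10, 5, fst = 0.1, sister_of = 2), "sister_of")
})

test_that("a planted sister population has a highly correlated frequency column", {
  fd <- make_synthetic_founders(4, 2000, 2, fst = 0.1, seed = 15,
                                sister_of = 2, sister_fst = 0.05)
  cm <- cor(fd$freqs)
  expect_gt(cm["pop2", "pop4"], 0.9)
  expect_gt(cm["pop2", "pop4"], max(cm["pop2", c("pop1", "pop3")]))
})

test_that("cohort-wide ancestry bookkeeping sums to one exactly", {
  fd <- small_founders(n_markers = 120, n_per_pop = 12)
  coh <- breed(fd$genotypes, fd$labels, breeding_scheme(c(10, 10, 10), 5, seed = 6))
  sums <- rowSums(as.matrix(coh$truth[c("pop1", "pop2")]))
  expect_true(all(sums == 1))
  expect_equal(nrow(coh$truth), 30)
  expect_identical(coh$truth$individual_id, individual_ids(coh$genotypes))
})
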