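test_that("objective is the squared residual norm", {
  X <- matrix(c(0, 2), 2, 1)
  expect_equal(cgr_objective(c(2, 0), X, 1), 8)      # (2-0)^2 + (0-2)^2
  b <- c(0.3, 0.7)
  X2 <- random_design(10, 2)
  expect_equal(cgr_objective(drop(X2 %*% b), X2, b), 0)
  expect_equal(cgr_objective(c(1, 2), X, 0), 5)      # b = 0 under the inequality mode
  expect_error(cgr_objective(c(1, 2, 3), X, 1), "dimension")
})

test_that("single-population equality fit is forced to one", {
  set.seed(3)
  y <- sample(0:2, 30, replace = TRUE)
  X <- matrix(runif(30, 0, 2), 30, 1)
  s <- solve_cgr(y, X, "eq")
  expect_equal(unname(s$b_hat), 1)
})

test_that("noise-free mixtures are recovered exactly in both modes", {
  set.seed(11)
  for (N in 2:6) {
    X <- random_design(80, N)
    b <- random_simplex(N)
    y <- drop(X %*% b)
    for (m in c("eq", "le")) {
      s <- solve_cgr(y, X, m)
      expect_lt(max(abs(s$b_hat - b)), 1e-6)
      expect_lt(s$rss, 1e-12)
      expect_equal(s$status, "converged")
    }
  }
  # the named two-component case
  X <- random_design(40, 2)
  y <- drop(X %*% c(0.25, 0.75))
  expect_equal(unname(solve_cgr(y, X, "eq")$b_hat), c(0.25, 0.75), tolerance = 1e-8)
})

test_that("an exact column match returns the unit vector", {
  set.seed(4)
  X <- random_design(60, 4)
  for (m in c("eq", "le")) {
    s <- solve_cgr(X[, 3], X, m)
    expect_equal(unname(s$b_hat), c(0, 0, 1, 0), tolerance = 1e-8)
  }
})

test_that("solution dominates simplex vertices and barycentre, and modes nest", {
  set.seed(9)
  for (i in 1:20) {
    N <- sample(2:5, 1)
    X <- random_design(40, N)
    y <- drop(X %*% random_simplex(N)) + rnorm(40, sd = 0.8)
    s_eq <- solve_cgr(y, X, "eq")
    s_le <- solve_cgr(y, X, "le")
    for (k in seq_len(N)) {
      ek <- replace(numeric(N), k, 1)
      expect_lte(s_eq$rss, cgr_objective(y, X, ek) + 1e-9)
    }
    expect_lte(s_eq$rss, cgr_objective(y, X, rep(1 / N, N)) + 1e-9)
    # inequality feasible set contains the simplex
    expect_lte(s_le$rss, s_eq$rss + 1e-9)
    expect_lt(abs(sum(s_eq$b_hat) - 1), 1e-6)
    expect_lte(sum(s_le$b_hat), 1 + 1e-6)
    expect_true(all(s_eq$b_hat >= 0), all(s_le$b_hat >= 0))
  }
})

test_that("permuting design columns permutes the estimate identically", {
  set.seed(21)
  X <- random_design(50, 4)
  y <- drop(X %*% random_simplex(4)) + rnorm(50, sd = 0.5)
  perm <- c(3, 1, 4, 2)
  for (m in c("eq", "le")) {
    b1 <- solve_cgr(y, X, m)$b_hat
    b2 <- solve_cgr(y, X[, perm], m)$b_hat
    expect_equal(unname(b2), unname(b1[perm]), tolerance = 1e-8)
  }
})

test_that("solver agrees with an independent quadratic-programming solver", {
  skip_if_not_installed("pracma")
  set.seed(33)
  for (i in 1:25) {
    N <- sample(2:6, 1)
    X <- random_design(60, N)
    y <- drop(X %*% random_simplex(N)) + rnorm(60, sd = 0.7)
    Q <- crossprod(X)
    qp <- pracma::quadprog(2 * Q, -2 * drop(crossprod(X, y)),
                           Aeq = matrix(1, 1, N), beq = 1, lb = rep(0, N))
    s <- solve_cgr(y, X, "eq")
    expect_equal(s$rss, cgr_objective(y, X, qp$xmin), tolerance = 1e-6)
    expect_equal(unname(s$b_hat), qp$xmin, tolerance = 1e-4)
  }
})

test_that("grid oracle enumerates the advertised grid and matches solve", {
  # step 0.5, N = 2 equality: exactly {(0,1),(0.5,0.5),(1,0)}
  X <- matrix(c(1, 0, 0, 1), 2, 2)
  o <- grid_oracle(c(0.4, 0.6), X, "eq", step = 0.5)
  expect_equal(unname(o), c(0.5, 0.5))
  o2 <- grid_oracle(c(0.9, 0.1), X, "eq", step = 0.5)
  expect_equal(unname(o2), c(1, 0))

  # exact column match is found at any step
  set.seed(6)
  X <- random_design(30, 3)
  expect_equal(unname(grid_oracle(X[, 1], X, "eq", step = 0.25)), c(1, 0, 0))

  expect_error(grid_oracle(rnorm(5), random_design(5, 5), "eq", 0.5), "at most 4")
  expect_error(grid_oracle(rnorm(5), random_design(5, 2), "eq", 0.3), "divide")
})

test_that("oracle never beats the solver by more than grid resolution allows", {
  set.seed(14)
  for (i in 1:10) {
    X <- random_design(50, 3)
    y <- drop(X %*% random_simplex(3)) + rnorm(50, sd = 0.5)
    for (m in c("eq", "le")) {
      s <- solve_cgr(y, X, m)
      o <- grid_oracle(y, X, m, step = 0.02)
      expect_gte(cgr_objective(y, X, o), s$rss - 1e-9)
    }
  }
})

test_that("missing genotypes are dropped pairwise before solving", {
  set.seed(8)
  X <- random_design(40, 3)
  b <- random_simplex(3)
  y <- drop(X %*% b)
  y[c(3, 17, 25)] <- NA
  s <- solve_cgr(y, X, "eq")
  expect_equal(s$n_markers, 37)
  expect_lt(max(abs(s$b_hat - b)), 1e-6)
  expect_error(solve_cgr(rep(NA_real_, 40), X, "eq"), "missing")
  expect_error(solve_cgr(y, X[, 0], "eq"), "zero columns")
})

test_that("duplicated design columns are flagged degenerate but still optimal", {
  set.seed(19)
  Xb <- random_design(50, 2)
  X <- cbind(Xb, Xb[, 2])  # third column duplicates the second
  y <- drop(Xb %*% c(0.4, 0.6)) + rnorm(50, sd = 0.3)
  s <- solve_cgr(y, X, "eq")
  expect_equal(s$status, "degenerate")
  # fit itself is still the optimum of the identifiable two-column problem
  s2 <- solve_cgr(y, Xb, "eq")
  expect_equal(s$rss, s2$rss, tolerance = 1e-8)
  expect_equal(unname(s$b_hat[1]), unname(s2$b_hat[1]), tolerance = 1e-6)
})

test_that("unconstrained diagnostic mode reproduces ordinary least squares", {
  set.seed(23)
  X <- random_design(50, 3)
  y <- drop(X %*% c(0.7, 0.5, -0.2)) + rnorm(50, sd = 0.2)
  s <- solve_cgr(y, X, "ols")
  expect_equal(unname(s$b_hat), unname(qr.solve(X, y)), tolerance = 1e-8)
})

test_that("cohort estimation matches per-individual solves and handles missing cells", {
  fd <- small_founders()
  panel <- estimate_frequencies(fd$genotypes, fd$labels)
  g <- subset_geno(fd$genotypes, individuals = individual_ids(fd$genotypes)[1:6])
  g$counts[5, 2] <- NA
  fit <- cgr_estimate(g, panel, "eq")
  expect_s3_class(fit$proportions, "tbl_df")
  expect_equal(nrow(fit$proportions), 6)
  for (j in c(1, 2)) {
    s <- solve_cgr(g$counts[, j], panel$design, "eq")
    expect_equal(unlist(fit$proportions[j, panel_populations(panel)]),
                 s$b_hat, tolerance = 1e-10)
    expect_equal(fit$details$rss[j], s$rss, tolerance = 1e-8)
  }
  expect_equal(fit$details$n_markers[2], nrow(panel$freqs) - 1)
  # equality-mode rows sum to exactly one after clipping
  sums <- rowSums(as.matrix(fit$proportions[panel_populations(panel)]))
  expect_equal(sums, rep(1, 6), tolerance = 1e-12)
})

test_that("tidy and glance views of a fit are consistent", {
  fd <- small_founders()
  panel <- estimate_frequencies(fd$genotypes, fd$labels)
  g <- subset_geno(fd$genotypes, individuals = individual_ids(fd$genotypes)[1:4])
  fit <- cgr_estimate(g, panel, "le")
  td <- tidy(fit)
  expect_named(td, c("individual_id", "population", "proportion"))
  expect_equal(nrow(td), 4 * 2)
  gl <- glance(fit)
  expect_equal(gl$n_individuals, 4)
  expect_equal(gl$constraint, "le")
})
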