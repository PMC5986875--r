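#' Residual sum of squares of a proportion vector
#'
#' The quantity the constrained regression minimises: the squared Euclidean
#' norm of `y - X %*% b`, in squared allele-count units.
#'
#' @param y numeric vector of observed allele counts, length M.
#' @param X M-by-N design matrix of expected allele contents.
#' @param b length-N coefficient vector.
#' @return A single non-negative number.
#' @export
cgr_objective <- function(y, X, b) {
  X <- as.matrix(X)
  if (length(y) != nrow(X) || length(b) != ncol(X)) {
    abort(sprintf("dimension mismatch: y has %d entries, X is %d x %d, b has %d.",
                  length(y), nrow(X), ncol(X), length(b)))
  }
  r <- y - drop(X %*% b)
  sum(r^2)
}

.grid_cache <- new.env(parent = emptyenv())

# ---- internal exact QP machinery on the normal equations -----------------
# Both routines minimise  f(b) = b'Qb - 2 c'b  (+ const) with Q = X'X, c = X'y,
# i.e. the least-squares objective, over their respective feasible sets.

.kkt_solve <- function(K, rhs) {
  out <- tryCatch(list(x = solve(K, rhs), singular = FALSE),
                  error = function(e) NULL)
  if (is.null(out)) out <- list(x = drop(MASS::ginv(K) %*% rhs), singular = TRUE)
  out
}

# Lawson-Hanson NNLS (normal-equation form): min f(b) s.t. b >= 0
.nnls_qc <- function(Q, c0) {
  N <- length(c0)
  b <- numeric(N)
  passive <- rep(FALSE, N)
  scale <- max(1, abs(c0))
  degenerate <- FALSE
  status <- "max_iter"
  for (outer in seq_len(30L * N + 30L)) {
    w <- c0 - drop(Q %*% b)                # -gradient/2
    cand <- which(!passive & w > 1e-10 * scale)
    if (!length(cand)) { status <- "converged"; break }
    passive[cand[which.max(w[cand])]] <- TRUE
    repeat {
      P <- which(passive)
      sol <- .kkt_solve(Q[P, P, drop = FALSE], c0[P])
      if (sol$singular) degenerate <- TRUE
      s <- sol$x
      if (all(s > 1e-12)) { b[] <- 0; b[P] <- s; break }
      neg <- which(s <= 1e-12)
      denom <- b[P][neg] - s[neg]
      alpha <- min(b[P][neg][denom > 0] / denom[denom > 0], 1)
      b[P] <- b[P] + alpha * (s - b[P])
      drop_idx <- P[b[P] <= 1e-12]
      if (!length(drop_idx)) drop_idx <- P[neg][which.min(s[neg])]
      passive[drop_idx] <- FALSE
      b[drop_idx] <- 0
      if (!any(passive)) { b[] <- 0; break }
    }
  }
  list(b = b, status = status, degenerate = degenerate)
}

# active-set QP: min f(b) s.t. sum(b) = 1, b >= 0
.simplex_eq_qc <- function(Q, c0) {
  N <- length(c0)
  if (N == 1) return(list(b = 1, status = "converged", degenerate = FALSE))
  b <- rep(1 / N, N)
  free <- rep(TRUE, N)
  scale <- max(1, abs(c0), abs(Q))
  degenerate <- FALSE
  status <- "max_iter"
  for (it in seq_len(50L * N + 50L)) {
    f <- which(free); nf <- length(f)
    K <- rbind(cbind(Q[f, f, drop = FALSE], rep(1, nf)), c(rep(1, nf), 0))
    sol <- .kkt_solve(K, c(c0[f], 1))
    if (sol$singular) degenerate <- TRUE
    bf <- sol$x[seq_len(nf)]
    lam <- sol$x[nf + 1L]
    if (all(bf >= -1e-12)) {
      b[] <- 0; b[f] <- pmax(bf, 0)
      if (all(free)) { status <- "converged"; break }
      g <- drop(Q %*% b) - c0
      mu <- g[!free] + lam
      if (all(mu >= -1e-9 * scale)) { status <- "converged"; break }
      free[which(!free)[which.min(mu)]] <- TRUE
    } else {
      cur <- b[f]
      d <- bf - cur
      blocking <- which(d < 0)
      alpha <- min(cur[blocking] / (-d[blocking]))
      alpha <- min(max(alpha, 0), 1)
      b[] <- 0
      b[f] <- pmax(cur + alpha * d, 0)
      hit <- f[which(d < 0 & b[f] <= 1e-12)]
      if (!length(hit)) hit <- f[blocking[which.min(cur[blocking] / (-d[blocking]))]]
      free[hit] <- FALSE
      b[hit] <- 0
      if (sum(free) == 0) { free[which.max(c0)] <- TRUE }
    }
  }
  list(b = b, status = status, degenerate = degenerate)
}

.solve_qc <- function(Q, c0, constraint) {
  if (constraint == "le") {
    res <- .nnls_qc(Q, c0)
    if (sum(res$b) <= 1 + 1e-9) return(res)
    eq <- .simplex_eq_qc(Q, c0)
    eq$degenerate <- eq$degenerate || res$degenerate
    return(eq)
  }
  .simplex_eq_qc(Q, c0)
}

# reduced-Hessian singularity check at the solution's support
.support_degenerate <- function(Q, b) {
  s <- which(b > 1e-8)
  if (length(s) < 2) return(FALSE)
  Qs <- Q[s, s, drop = FALSE]
  qr(Qs, tol = 1e-10)$rank < length(s)
}

.finalise_b <- function(b, constraint) {
  b[b < 0 & b > -1e-8] <- 0
  b[b < 0] <- 0   # solver guarantees entries >= -1e-12 anyway
  if (constraint == "eq" && sum(b) > 0) b <- b / sum(b)
  if (constraint == "le" && sum(b) > 1) b <- b / sum(b)
  b
}

#' Solve the simplex-constrained least-squares problem for one individual
#'
#' Finds the global minimiser of \eqn{\lVert y - Xb \rVert^2} over either the
#' unit simplex (`"eq"`: \eqn{b \ge 0}, \eqn{\sum_k b_k = 1}) or its
#' sub-unit relaxation (`"le"`: \eqn{b \ge 0}, \eqn{\sum_k b_k \le 1}).
#' The objective is a convex quadratic with linear constraints, solved
#' exactly by an active-set method on the normal equations; the `"le"` mode
#' first solves the non-negativity-only problem (Lawson-Hanson) and falls
#' back to the sum-to-one face only when that optimum oversteps it.
#' `"ols"` returns the unconstrained least-squares coefficients as a
#' diagnostic — they may be negative and are not proportions.
#'
#' Missing entries of `y` are handled by pairwise deletion: the marker rows
#' are dropped from both `y` and `X` before solving.
#'
#' @inheritParams cgr_objective
#' @param constraint `"eq"`, `"le"`, or `"ols"` (diagnostic).
#' @return A list with elements `b_hat` (named like the columns of `X`),
#'   `rss`, `status` (`"converged"`, `"degenerate"` if the reduced Hessian on
#'   the solution's support is singular — individual coefficients then not
#'   identifiable although the fit is optimal — or `"max_iter"`), and
#'   `n_markers` used after deletion.
#' @export
solve_cgr <- function(y, X, constraint = c("eq", "le", "ols")) {
  constraint <- match.arg(constraint)
  X <- as.matrix(X)
  if (ncol(X) == 0) abort("design matrix has zero columns.")
  if (length(y) != nrow(X)) abort("length(y) must equal nrow(X).")
  keep <- !is.na(y)
  if (!any(keep)) abort("all genotypes missing for this individual.")
  y <- y[keep]; Xk <- X[keep, , drop = FALSE]
  if (nrow(Xk) < ncol(Xk)) {
    warn(sprintf("fewer markers (%d) than populations (%d); coefficients may not be identifiable.",
                 nrow(Xk), ncol(Xk)))
  }
  Q <- crossprod(Xk)
  c0 <- drop(crossprod(Xk, y))
  res <- .solve_cell(Q, c0, sum(y^2), constraint, colnames(X))
  res$n_markers <- nrow(Xk)
  res
}

# shared core used by solve_cgr and cgr_estimate (Q = X'X, c0 = X'y, yty = y'y)
.solve_cell <- function(Q, c0, yty, constraint, pops) {
  if (constraint == "ols") {
    sol <- .kkt_solve(Q, c0)
    b <- sol$x
    status <- if (sol$singular) "degenerate" else "converged"
  } else {
    r <- .solve_qc(Q, c0, constraint)
    b <- .finalise_b(r$b, constraint)
    status <- if (r$status != "converged") r$status
              else if (r$degenerate || .support_degenerate(Q, b)) "degenerate"
              else "converged"
  }
  rss <- max(yty - 2 * sum(c0 * b) + drop(crossprod(b, Q %*% b)), 0)
  names(b) <- pops
  list(b_hat = b, rss = rss, status = status, constraint = constraint)
}

#' Estimate founder genome proportions for a cohort
#'
#' Applies [solve_cgr()] to every individual of a genotype matrix against a
#' founder panel. Markers are matched by id between genotypes and panel
#' (panel order); the cross-products are shared across individuals without
#' missing genotypes, so cost grows only linearly in cohort size.
#'
#' @param genotypes a [geno_matrix()] of target (admixed) individuals.
#' @param panel a [founder_panel()] on the same counted alleles (use
#'   [align_markers()] against the reference first if in doubt).
#' @param constraint `"eq"` (proportions sum to one), `"le"` (sum at most
#'   one — more robust when contributing populations may be missing from the
#'   panel), or `"ols"` (unconstrained diagnostic; not proportions).
#' @return An object of class `cgr_fit`: a list with
#'   \describe{
#'     \item{proportions}{tibble, `individual_id` + one column per population
#'       (clipped to zero at -1e-8 and, in `"eq"` mode, renormalised to sum
#'       exactly one).}
#'     \item{details}{tibble with per-individual `rss`, `status`,
#'       `n_markers`.}
#'     \item{constraint, populations}{the mode and population order.}
#'   }
#'   Use [tidy()] for a long view, [glance()] for a one-row summary.
#' @export
cgr_estimate <- function(genotypes, panel, constraint = c("eq", "le", "ols")) {
  constraint <- match.arg(constraint)
  stopifnot(inherits(genotypes, "geno_matrix"), inherits(panel, "founder_panel"))
  common <- intersect(rownames(panel$freqs), marker_ids(genotypes))
  if (!length(common)) abort("no markers shared between genotypes and panel.")
  if (length(common) < nrow(panel$freqs)) {
    inform(sprintf("cgr_estimate: using %d of %d panel markers present in the genotypes.",
                   length(common), nrow(panel$freqs)))
  }
  X <- panel$design[common, , drop = FALSE]
  Y <- genotypes$counts[common, , drop = FALSE]
  pops <- colnames(X)
  Q_all <- crossprod(X)
  ids <- colnames(Y)
  has_na <- colSums(is.na(Y)) > 0

  one <- function(j) {
    yj <- Y[, j]
    if (has_na[j]) {
      keep <- !is.na(yj)
      if (!any(keep)) abort(sprintf("all genotypes missing for individual '%s'.", ids[j]))
      Xk <- X[keep, , drop = FALSE]
      .solve_cell(crossprod(Xk), drop(crossprod(Xk, yj[keep])), sum(yj[keep]^2),
                  constraint, pops)
    } else {
      .solve_cell(Q_all, drop(crossprod(X, yj)), sum(yj^2), constraint, pops)
    }
  }
  sols <- lapply(seq_along(ids), one)

  bmat <- do.call(rbind, lapply(sols, `[[`, "b_hat"))
  proportions <- as_tibble(as.data.frame(bmat))
  names(proportions) <- pops
  proportions <- dplyr::bind_cols(tibble(individual_id = ids), proportions)
  details <- tibble(
    individual_id = ids,
    rss = vapply(sols, `[[`, numeric(1), "rss"),
    status = vapply(sols, `[[`, character(1), "status"),
    n_markers = unname(colSums(!is.na(Y)))
  )
  structure(
    list(proportions = proportions, details = details,
         constraint = constraint, populations = pops),
    class = "cgr_fit"
  )
}

#' @export
print.cgr_fit <- function(x, ...) {
  cat(sprintf("<cgr_fit> %d individuals x %d populations, constraint = %s\n",
              nrow(x$proportions), length(x$populations), x$constraint))
  print(head(x$proportions, 5))
  invisible(x)
}

#' @method tidy cgr_fit
#' @export
tidy.cgr_fit <- function(x, ...) {
  tidyr::pivot_longer(x$proportions, -"individual_id",
                      names_to = "population", values_to = "proportion")
}

#' @method glance cgr_fit
#' @export
glance.cgr_fit <- function(x, ...) {
  tibble(
    n_individuals = nrow(x$proportions),
    n_populations = length(x$populations),
    constraint = x$constraint,
    mean_rss = mean(x$details$rss),
    n_degenerate = sum(x$details$status == "degenerate"),
    n_nonconverged = sum(x$details$status == "max_iter")
  )
}

#' @method as_tibble cgr_fit
#' @export
as_tibble.cgr_fit <- function(x, ...) x$proportions

#' Exhaustive grid search oracle for the constrained regression
#'
#' Enumerates the feasible set on a regular grid of resolution `step`
#' (equality mode: all compositions of 1; inequality mode: all grid points
#' with coordinate sum at most 1) and returns the objective-minimising grid
#' point; ties are broken by the lexicographically smallest vector. Intended
#' for verifying [solve_cgr()] at small N — cost is combinatorial, so N is
#' capped at 4. In inequality mode the last coordinate is minimised
#' analytically over its grid range (the objective is quadratic in a single
#' coordinate), which searches the identical grid without materialising it.
#'
#' @inheritParams cgr_objective
#' @param constraint `"eq"` or `"le"`.
#' @param step grid resolution; must divide 1.
#' @return The minimising proportion vector (named like the columns of `X`).
#' @export
grid_oracle <- function(y, X, constraint = c("eq", "le"), step = 0.01) {
  constraint <- match.arg(constraint)
  X <- as.matrix(X)
  N <- ncol(X)
  if (N > 4) abort("grid_oracle supports at most 4 populations.")
  K <- round(1 / step)
  if (abs(K * step - 1) > 1e-8) abort("`step` must divide 1.")
  keep <- !is.na(y)
  y <- y[keep]; X <- X[keep, , drop = FALSE]
  Q <- crossprod(X); c0 <- drop(crossprod(X, y)); yty <- sum(y^2)

  if (N == 1) {
    cand <- if (constraint == "eq") 1 else seq(0, 1, by = step)
    obj <- yty - 2 * c0 * cand + Q[1, 1] * cand^2
    b <- cand[which.min(obj)]
    return(stats::setNames(b, colnames(X)))
  }

  # integer grid over the first N-1 coordinates, partial sums <= K
  # (cached across calls: repeated verification sweeps reuse one enumeration)
  key <- sprintf("N%d_K%d", N, K)
  prefix <- .grid_cache[[key]]
  if (is.null(prefix)) {
    levels <- 0:K
    prefix <- as.matrix(do.call(expand.grid, rep(list(levels), N - 1)))
    prefix <- prefix[rowSums(prefix) <= K, , drop = FALSE]
    if (nrow(prefix) > 2e7) abort("grid too large; increase `step`.")
    dimnames(prefix) <- NULL
    .grid_cache[[key]] <- prefix
  }
  U <- prefix * step                           # P x (N-1)
  cu <- c0[seq_len(N - 1)]
  Quu <- Q[seq_len(N - 1), seq_len(N - 1), drop = FALSE]
  qNu <- Q[N, seq_len(N - 1)]
  base <- yty - 2 * drop(U %*% cu) + rowSums((U %*% Quu) * U)
  a <- drop(U %*% qNu)                         # cross term coefficient
  qNN <- Q[N, N]
  tmax <- (K - rowSums(prefix))                # in grid units

  evalf <- function(tk) base - 2 * c0[N] * (tk * step) + 2 * a * (tk * step) + qNN * (tk * step)^2

  if (constraint == "eq") {
    tk <- tmax
    obj <- evalf(tk)
    B <- cbind(U, tk * step)
  } else {
    if (qNN > 1e-12) {
      tstar <- (c0[N] - a) / qNN / step
      lo <- pmin(pmax(floor(tstar), 0), tmax)
      hi <- pmin(pmax(ceiling(tstar), 0), tmax)
    } else {
      slope <- 2 * a - 2 * c0[N]               # linear coefficient in t
      lo <- numeric(nrow(U))
      hi <- ifelse(slope < 0, tmax, 0)
    }
    olo <- evalf(lo); ohi <- evalf(hi)
    # prefer the smaller last coordinate on exact ties (lexicographic)
    use_hi <- ohi < olo
    tk <- ifelse(use_hi, hi, lo)
    obj <- ifelse(use_hi, ohi, olo)
    B <- cbind(U, tk * step)
  }
  best <- min(obj)
  ties <- which(obj == best)
  if (length(ties) > 1) {
    ord <- do.call(order, as.data.frame(B[ties, , drop = FALSE]))
    pick <- ties[ord[1]]
  } else pick <- ties
  stats::setNames(B[pick, ], colnames(X))
}
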