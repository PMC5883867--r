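# Shared fixtures, generated in code. Cohorts are memoised per test run so
# several test files can reuse the same simulation without re-paying for it.

toy_genotypes <- function(dosage, chr = NULL, pos = NULL, origin = "POP1",
                          a1 = "A", a2 = "G") {
  dosage <- as.matrix(dosage)
  n <- nrow(dosage); m <- ncol(dosage)
  if (is.null(chr)) chr <- rep("1", m)
  if (is.null(pos)) pos <- ave(seq_len(m), chr, FUN = seq_along) * 1000
  ids <- sprintf("t%03d", seq_len(n))
  snps <- if (!is.null(colnames(dosage))) colnames(dosage) else
    sprintf("m%03d", seq_len(m))
  a1 <- rep_len(a1, m); a2 <- rep_len(a2, m)
  genotype_dataset(
    matrix(as.integer(dosage), n, m, dimnames = list(ids, snps)),
    tibble::tibble(snp = snps, chr = chr, pos = as.numeric(pos),
                   a1 = a1, a2 = a2),
    tibble::tibble(id = ids, sex = rep_len(c("M", "F"), n),
                   origin = rep_len(origin, n)))
}

.fixture_env <- new.env(parent = emptyenv())

memo_fixture <- function(name, fn) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, fn(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# small two-population cohort reused across modules
small_cohort <- function() {
  memo_fixture("small_cohort", function() {
    simulate_cohort(sim_config(n_pop1 = 200, n_pop2 = 80, n_snps = 400,
                               n_chromosomes = 5, n_qtl = 40, seed = 42))
  })
}

small_grm <- function() {
  memo_fixture("small_grm", function() {
    compute_grm(small_cohort()$genotypes, ridge = 0.01)
  })
}

# deterministic 12-sample REML fixture: a fixed simulated G and y
reml_fixture <- function() {
  memo_fixture("reml_fixture", function() {
    set.seed(2024)
    n <- 12
    L <- matrix(rnorm(n * 30), n, 30) / sqrt(30)
    G <- tcrossprod(L)
    G <- G / mean(diag(G))
    diag(G) <- diag(G) + 0.01
    rownames(G) <- colnames(G) <- sprintf("f%02d", seq_len(n))
    W <- cbind(`(Intercept)` = 1, x = rbinom(n, 1, 0.5))
    u <- drop(chol(G + diag(1e-8, n))) # not used; keep G pd
    g <- drop(t(chol(0.6 * G)) %*% rnorm(n))
    y <- drop(W %*% c(1, 0.5)) + g + rnorm(n, 0, sqrt(0.4))
    list(y = y, W = W, G = G)
  })
}

# brute-force restricted-likelihood maximization on a 2-d grid + refinement;
# independent of the AI-REML path (direct likelihood evaluations only)
grid_reml <- function(y, W, G, lower = 1e-4, upper = NULL) {
  if (is.null(upper)) upper <- 3 * var(y)
  ll <- function(sg2, se2) {
    n <- length(y)
    V <- sg2 * G + diag(se2, n)
    R <- tryCatch(chol(V), error = function(e) return(NULL))
    if (is.null(R)) return(-Inf)
    Vi <- chol2inv(R)
    WtViW <- t(W) %*% Vi %*% W
    a <- solve(WtViW, t(W) %*% Vi %*% y)
    r <- y - W %*% a
    -0.5 * (2 * sum(log(diag(R))) + determinant(WtViW)$modulus +
            t(r) %*% Vi %*% r)[1]
  }
  grid <- seq(lower, upper, length.out = 40)
  best <- c(grid[1], grid[1]); best_ll <- -Inf
  for (a in grid) for (b in grid) {
    v <- ll(a, b)
    if (v > best_ll) { best_ll <- v; best <- c(a, b) }
  }
  # refine with a derivative-free simplex on the same likelihood surface
  o <- optim(best, function(th) {
    if (any(th <= 0)) return(1e10)
    -ll(th[1], th[2])
  }, method = "Nelder-Mead", control = list(reltol = 1e-14, maxit = 2000))
  best <- o$par
  list(sigma_g2 = best[1], sigma_e2 = best[2], loglik = ll(best[1], best[2]))
}
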