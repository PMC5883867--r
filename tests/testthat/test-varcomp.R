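# AI-REML variance components, heritability, BLUP prediction.

test_that("AI-REML matches brute-force restricted-likelihood maximization", {
  fx <- reml_fixture()
  fit <- fit_aireml(fx$y, fx$W, fx$G)
  oracle <- grid_reml(fx$y, fx$W, fx$G)
  expect_true(fit$converged)
  expect_equal(fit$sigma_g2, oracle$sigma_g2, tolerance = 1e-3,
               ignore_attr = TRUE)
  expect_equal(fit$sigma_e2, oracle$sigma_e2, tolerance = 1e-3,
               ignore_attr = TRUE)
  expect_gte(fit$loglik, oracle$loglik - 1e-6)
})

test_that("noise-free phenotypes drive both components to the floor", {
  fx <- reml_fixture()
  y <- drop(fx$W %*% c(2, -1))
  fit <- fit_aireml(y, fx$W, fx$G)
  expect_true(fit$boundary)
  expect_equal(fit$sigma_g2, fit$var_floor)
  expect_equal(fit$sigma_e2, fit$var_floor)
})

test_that("restricted log-likelihood never decreases along the trace", {
  fx <- reml_fixture()
  fit <- fit_aireml(fx$y, fx$W, fx$G)
  lls <- fit$trace$loglik
  expect_true(all(diff(lls) > -1e-8))
  expect_gte(lls[length(lls)], lls[1])
})

test_that("estimates are invariant to reordering individuals", {
  fx <- reml_fixture()
  fit1 <- fit_aireml(fx$y, fx$W, fx$G)
  set.seed(9)
  p <- sample(length(fx$y))
  fit2 <- fit_aireml(fx$y[p], fx$W[p, ], fx$G[p, p])
  expect_equal(fit1$sigma_g2, fit2$sigma_g2, tolerance = 1e-6)
  expect_equal(fit1$sigma_e2, fit2$sigma_e2, tolerance = 1e-6)
  expect_equal(fit1$loglik, fit2$loglik, tolerance = 1e-6)
})

test_that("heritability follows the delta-method formula exactly", {
  # sigma_g2 = sigma_e2 = 1, se_g = 0.2, se_e = 0, cov = 0:
  # h2 = 0.5; se = |dh2/dsg2| * se_g = (1/4) * 0.2 = 0.05
  fake <- list(sigma_g2 = 1, sigma_e2 = 1,
               ai_cov = matrix(c(0.04, 0, 0, 0), 2, 2))
  h <- heritability(fake)
  expect_equal(h$h2, 0.5)
  expect_equal(h$se, 0.05)
  # sigma_e2 = 0 limit
  h1 <- heritability(list(sigma_g2 = 2, sigma_e2 = 0,
                          ai_cov = matrix(0, 2, 2)))
  expect_equal(h1$h2, 1)
  expect_error(heritability(list(sigma_g2 = 0, sigma_e2 = 0,
                                 ai_cov = NULL)), "undefined")
})

test_that("delta-method SE agrees with numerical differentiation", {
  fx <- reml_fixture()
  fit <- fit_aireml(fx$y, fx$W, fx$G)
  h2_of <- function(th) th[1] / (th[1] + th[2])
  eps <- 1e-6
  th <- c(fit$sigma_g2, fit$sigma_e2)
  grad <- sapply(1:2, function(k) {
    up <- th; up[k] <- up[k] + eps
    dn <- th; dn[k] <- dn[k] - eps
    (h2_of(up) - h2_of(dn)) / (2 * eps)
  })
  se_num <- sqrt(drop(t(grad) %*% fit$ai_cov %*% grad))
  expect_equal(heritability(fit)$se, se_num, tolerance = 1e-8)
})

test_that("a validation row duplicating a training row reproduces its BLUP", {
  fx <- reml_fixture()
  n <- length(fx$y)
  fit <- fit_aireml(fx$y, fx$W, fx$G)
  # append a pseudo-individual with a duplicated G row/column
  K <- rbind(cbind(fx$G, fx$G[, n]), c(fx$G[n, ], fx$G[n, n]))
  ids <- c(rownames(fx$G), "dup")
  dimnames(K) <- list(ids, ids)
  pred <- blup_predict(fit, K, "dup")
  expect_equal(pred$u, unname(fit$u[n]), tolerance = 1e-8)
})

test_that("GBLUP equals ridge-regression on markers (SNP-BLUP duality)", {
  set.seed(31)
  n <- 30; m <- 50
  X <- matrix(rbinom(n * m, 2, 0.4), n, m)
  p <- colMeans(X) / 2
  Z <- sweep(X, 2, 2 * p, "-")
  cdenom <- 2 * sum(p * (1 - p))
  G <- tcrossprod(Z) / cdenom
  ids <- sprintf("s%02d", 1:n)
  dimnames(G) <- list(ids, ids)
  W <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  y <- rnorm(n, 2, 1) + Z %*% rnorm(m, 0, 0.2)
  sg2 <- 0.5; se2 <- 0.7

  sol <- gblup_solve(y, W, G, sg2, se2)
  # ridge regression of marker effects with lambda = cdenom * se2 / sg2
  lam <- cdenom * se2 / sg2
  yc <- y - W %*% solve(t(W) %*% solve(sg2 * G + diag(se2, n), W),
                        t(W) %*% solve(sg2 * G + diag(se2, n), y))
  a_hat <- solve(crossprod(Z) + diag(lam, m), crossprod(Z, yc))
  expect_equal(unname(sol$u), drop(Z %*% a_hat), tolerance = 1e-6)
})

test_that("conditional-expectation prediction equals the missing-record MME", {
  set.seed(32)
  n <- 30
  L <- matrix(rnorm(n * 40), n, 40) / sqrt(40)
  G <- tcrossprod(L); G <- G / mean(diag(G)); diag(G) <- diag(G) + 0.05
  ids <- sprintf("q%02d", 1:n)
  dimnames(G) <- list(ids, ids)
  W <- cbind(`(Intercept)` = rep(1, n))
  y <- drop(t(chol(0.5 * G)) %*% rnorm(n)) + rnorm(n, 1, sqrt(0.5))
  tr <- 1:22; va <- 23:30
  sg2 <- 0.5; se2 <- 0.5

  fit <- list(ids = ids[tr],
              u = gblup_solve(y[tr], W[tr, , drop = FALSE],
                              G[tr, tr], sg2, se2)$u,
              alpha = NULL, fixed_names = "(Intercept)")
  class(fit) <- "reml_fit"
  pred <- blup_predict(fit, G, ids[va])

  # Henderson's MME over all n individuals with validation records absent:
  # [W'R-W  W'R-]   [a]   [W'R-y]
  # [R-W  R- + G^-1/sg2] [u] = [R-y]  with R- having zeros for missing rows
  Rinv <- diag(c(rep(1 / se2, length(tr)), rep(0, length(va))))
  ord <- c(tr, va)
  Go <- G[ord, ord]
  Wo <- W[ord, , drop = FALSE]
  yo <- c(y[tr], rep(0, length(va)))
  lhs <- rbind(
    cbind(t(Wo) %*% Rinv %*% Wo, t(Wo) %*% Rinv),
    cbind(Rinv %*% Wo, Rinv + solve(Go) / sg2))
  rhs <- c(t(Wo) %*% Rinv %*% yo, Rinv %*% yo)
  sol <- solve(lhs, rhs)
  u_mme <- sol[-1][match(va, ord)]
  expect_equal(unname(pred$u), unname(u_mme), tolerance = 1e-6)
})

test_that("prediction errors on overlapping or unknown validation ids", {
  fx <- reml_fixture()
  fit <- fit_aireml(fx$y, fx$W, fx$G)
  expect_error(blup_predict(fit, fx$G, rownames(fx$G)[1]), "overlap")
  expect_error(blup_predict(fit, fx$G, "ghost"), "absent from the GRM")
})

test_that("BLUP accuracy grows with nested training sets", {
  co <- small_cohort()
  g <- small_grm()
  ph <- co$phenotypes
  val <- ph$id[261:280]
  sizes <- c(60, 130, 260)
  acc <- sapply(sizes, function(ns) {
    tr <- ph[1:ns, ]
    Kt <- g$K[tr$id, tr$id]
    fit <- fit_aireml(tr$score_mean, jointgp:::design_matrix(tr), Kt)
    pred <- blup_predict(fit, g, val)
    cor(pred$u, ph$true_bv[match(val, ph$id)])
  })
  expect_gt(acc[3], acc[1])
})

test_that("single-origin training drops the aliased origin column", {
  co <- small_cohort()
  g <- small_grm()
  tr <- dplyr::filter(co$phenotypes, origin == "POP1")
  fit <- fit_aireml(tr$score_mean, jointgp:::design_matrix(tr),
                    g$K[tr$id, tr$id])
  expect_false("origin2" %in% fit$fixed_names)
  expect_true("sexM" %in% fit$fixed_names)
})
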