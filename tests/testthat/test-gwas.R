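# Mixed-model GWAS and SNP-subset preselection.

test_that("with no polygenic variance the scan reduces to OLS", {
  co <- small_cohort()
  geno <- subset_genotypes(co$genotypes, snps = 1:40)
  g <- small_grm()
  ph <- co$phenotypes
  out <- fit_lmm_gwas(ph, geno, g, lambda = 0)
  W <- jointgp:::design_matrix(ph)
  for (j in c(1, 7, 23)) {
    x <- geno$dosage[, j]
    if (var(x) == 0) next
    ols <- lm(ph$score_mean ~ 0 + W + x)
    sm <- summary(ols)$coefficients
    expect_equal(out$beta[j], sm["x", "Estimate"], tolerance = 1e-8,
                 ignore_attr = TRUE)
    expect_equal(out$se[j], sm["x", "Std. Error"], tolerance = 1e-8,
                 ignore_attr = TRUE)
    p_oracle <- pchisq((sm["x", "Estimate"] / sm["x", "Std. Error"])^2,
                       1, lower.tail = FALSE)
    expect_equal(out$p[j], p_oracle, tolerance = 1e-8)
  }
})

test_that("permuted phenotypes give uniform p-values", {
  co <- small_cohort()
  g <- small_grm()
  set.seed(17)
  ph <- co$phenotypes
  ph$score_mean <- sample(ph$score_mean)
  out <- fit_lmm_gwas(ph, co$genotypes, g)
  p <- out$p[!is.na(out$p)]
  ks <- suppressWarnings(ks.test(p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("p-values and ranks are invariant to rescaling the phenotype", {
  co <- small_cohort()
  geno <- subset_genotypes(co$genotypes, snps = 1:60)
  g <- small_grm()
  ph <- co$phenotypes
  out1 <- fit_lmm_gwas(ph, geno, g, lambda = 0.4)
  ph2 <- ph
  ph2$score_mean <- 3 * ph2$score_mean + 7
  out2 <- fit_lmm_gwas(ph2, geno, g, lambda = 0.4)
  expect_equal(out2$p, out1$p, tolerance = 1e-10)
  expect_identical(out2$rank, out1$rank)
  expect_equal(out2$beta, 3 * out1$beta, tolerance = 1e-10)
})

test_that("rotated GLS matches direct generalized least squares on a toy", {
  set.seed(23)
  n <- 40
  L <- matrix(rnorm(n * 50), n, 50) / sqrt(50)
  K <- tcrossprod(L); K <- K / mean(diag(K)); diag(K) <- diag(K) + 0.01
  ids <- sprintf("g%02d", 1:n)
  dimnames(K) <- list(ids, ids)
  x <- rbinom(n, 2, 0.5)
  dos <- cbind(x, rbinom(n, 2, 0.3))
  colnames(dos) <- c("sA", "sB"); rownames(dos) <- ids
  geno <- genotype_dataset(
    dos, tibble::tibble(snp = c("sA", "sB"), chr = "1", pos = c(1e3, 2e3),
                        a1 = "A", a2 = "G"),
    tibble::tibble(id = ids, sex = rep_len(c("M", "F"), n), origin = "P"))
  ph <- tibble::tibble(id = ids, sex = geno$meta$sex, origin = "P",
                       score_mean = rnorm(n, 2) + 0.3 * x)
  lambda <- 0.7
  out <- fit_lmm_gwas(ph, geno, structure(list(K = K), class = "grm"),
                      lambda = lambda)
  # direct GLS with V = lambda*K + I (V-scale cancels in beta and Wald)
  V <- lambda * K + diag(n)
  Vi <- solve(V)
  W <- jointgp:::design_matrix(ph)
  W <- W[, apply(W, 2, var) > 0 | colnames(W) == "(Intercept)", drop = FALSE]
  X <- cbind(W, x)
  XtVi <- t(X) %*% Vi
  bhat <- solve(XtVi %*% X, XtVi %*% ph$score_mean)
  resid <- ph$score_mean - X %*% bhat
  sigma2 <- drop(t(resid) %*% Vi %*% resid) / (n - ncol(X))
  covb <- sigma2 * solve(XtVi %*% X)
  expect_equal(out$beta[1], bhat[ncol(X)], tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(out$se[1], sqrt(covb[ncol(X), ncol(X)]), tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("subset selection is deterministic, top-k and nested", {
  fake <- tibble::tibble(
    snp = sprintf("s%02d", 1:10), chr = "1", pos = 1:10 * 100,
    beta = rnorm(10), se = 1, wald = rnorm(10)^2,
    p = c(0.5, 0.01, 0.3, 0.002, 0.9, 0.04, 0.6, 0.11, 0.22, 0.77))
  fake$rank <- rank(fake$p)
  class(fake) <- c("gwas_result", class(fake))
  top3 <- select_subset(fake, 0.3, "preselected")
  expect_equal(sort(top3$snp_ids), sort(c("s04", "s02", "s06")))
  # nesting: fraction 0.2 subset of fraction 0.5 subset
  s2 <- select_subset(fake, 0.2, "preselected")
  s5 <- select_subset(fake, 0.5, "preselected")
  expect_true(all(s2$snp_ids %in% s5$snp_ids))
  # fraction 1 returns the full panel in both modes
  expect_setequal(select_subset(fake, 1, "preselected")$snp_ids, fake$snp)
  expect_setequal(select_subset(fake, 1, "random")$snp_ids, fake$snp)
  # random mode: seeded determinism
  r1 <- select_subset(fake, 0.5, "random", seed = 4)
  r2 <- select_subset(fake, 0.5, "random", seed = 4)
  r3 <- select_subset(fake, 0.5, "random", seed = 5)
  expect_identical(r1$snp_ids, r2$snp_ids)
  expect_false(identical(r1$snp_ids, r3$snp_ids))
  expect_error(select_subset(fake, 0.01, "preselected"), "zero SNPs")
})

test_that("fraction-1 subset experiment reproduces the all-SNP baseline", {
  co <- small_cohort()
  sub <- subset_prediction_experiment(
    co$phenotypes, co$genotypes, fractions = 1,
    modes = c("preselected", "random"), k = 3, seed = 5)
  pre <- dplyr::filter(sub, mode == "preselected")
  ran <- dplyr::filter(sub, mode == "random")
  merged <- dplyr::inner_join(pre, ran, by = c("fold", "validation_origin"))
  expect_equal(merged$rho.x, merged$rho.y, tolerance = 1e-8)
  expect_equal(merged$mse.x, merged$mse.y, tolerance = 1e-8)
})

test_that("leakage-free subset prediction shows no signal on permuted data", {
  co <- small_cohort()
  set.seed(41)
  ph <- co$phenotypes
  ph$score_mean <- sample(ph$score_mean)
  sub <- subset_prediction_experiment(
    ph, co$genotypes, fractions = c(0.1, 0.5),
    modes = "preselected", k = 3, seed = 6)
  agg <- sub |>
    dplyr::group_by(fraction) |>
    dplyr::summarise(rho = mean(rho, na.rm = TRUE))
  # with ranking confined to training folds, preselection cannot
  # manufacture accuracy from null data at any fraction
  n_val <- min(sub$n_snps * 0 + 93)  # smallest validation fold ~ n/3
  expect_true(all(abs(agg$rho) < 2 / sqrt(60)))
})

test_that("both selection modes converge to the all-SNP accuracy", {
  co <- small_cohort()
  sub <- subset_prediction_experiment(
    co$phenotypes, co$genotypes, fractions = c(0.05, 1),
    modes = c("preselected", "random"), k = 3,
    random_replicates = 3, seed = 8)
  agg <- sub |>
    dplyr::group_by(fraction, mode) |>
    dplyr::summarise(rho = mean(rho, na.rm = TRUE), .groups = "drop")
  rho_all <- agg$rho[agg$fraction == 1]
  expect_equal(rho_all[1], rho_all[2], tolerance = 1e-8)
  expect_true(all(is.finite(agg$rho)))
})
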