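# Genomic relationship matrix, PCA stratification, F_ST, LD consistency.

test_that("GRM matches the hand-evaluated 2x2 VanRaden case", {
  # 2 individuals, 1 polymorphic SNP with dosages (0, 2), in-sample p = 0.5:
  # Z = (-1, 1), denom = 2 * 0.5 * 0.5 = 0.5 -> G = [[2,-2],[-2,2]].
  # A second constant-difference SNP pair is needed because a single SNP
  # panel is rejected; use two identical SNPs and halve.
  d <- toy_genotypes(cbind(s1 = c(0, 2), s2 = c(0, 2)), pos = c(100, 200))
  g <- compute_grm(d, ridge = 0)
  expect_equal(unname(g$K), matrix(c(2, -2, -2, 2), 2), tolerance = 1e-12)
})

test_that("GRM centering identity and ridge behave exactly", {
  geno <- small_cohort()$genotypes
  g0 <- compute_grm(geno, ridge = 0)
  n <- nrow(g0$K)
  expect_lt(abs(sum(g0$K)), 1e-8 * n^2)
  expect_equal(unname(g0$K), unname(t(g0$K)), tolerance = 1e-12)
  g1 <- compute_grm(geno, ridge = 0.01)
  expect_equal(diag(g1$K), diag(g0$K) + 0.01, tolerance = 1e-12)
  expect_equal(g1$K[lower.tri(g1$K)], g0$K[lower.tri(g0$K)], tolerance = 1e-12)
})

test_that("GRM is PSD at ridge 0 and PD at ridge 0.01", {
  K0 <- compute_grm(small_cohort()$genotypes, ridge = 0)$K
  ev <- eigen(K0, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-8 * sum(diag(K0)))
  K1 <- K0; diag(K1) <- diag(K1) + 0.01
  expect_silent(chol(K1))
})

test_that("mean GRM diagonal is near 1 for a single drifted population", {
  co <- small_cohort()
  pop1 <- subset_genotypes(co$genotypes,
                           samples = which(co$genotypes$meta$origin == "POP1"))
  g <- compute_grm(pop1, ridge = 0)
  expect_gt(mean(diag(g$K)), 0.9)
  expect_lt(mean(diag(g$K)), 1.1)
})

test_that("group summary reproduces hand-computed block means", {
  K <- matrix(c(1.0, 0.2, 0.3,
                0.2, 1.1, 0.4,
                0.3, 0.4, 0.9), 3, 3,
              dimnames = list(letters[1:3], letters[1:3]))
  g <- structure(list(K = K), class = "grm")
  s <- grm_group_summary(g, c("A", "A", "B"))
  get <- function(g1, g2, part) {
    r <- s[s$group1 == g1 & s$group2 == g2 & s$part == part, ]
    r$mean
  }
  expect_equal(get("A", "A", "diagonal"), mean(c(1.0, 1.1)))
  expect_equal(get("A", "A", "off_diagonal"), 0.2)
  expect_equal(get("B", "B", "diagonal"), 0.9)
  expect_true(is.na(get("B", "B", "off_diagonal")))  # singleton group
  expect_equal(get("A", "B", "off_diagonal"), mean(c(0.3, 0.4)))
  # identity matrix sanity
  gI <- structure(list(K = diag(4)), class = "grm")
  sI <- grm_group_summary(gI, rep("X", 4))
  expect_equal(sI$mean[sI$part == "diagonal"], 1)
  expect_equal(sI$mean[sI$part == "off_diagonal"], 0)
})

test_that("PCA scores are orthogonal with sorted explained fractions", {
  pc <- pca_genotypes(small_cohort()$genotypes, k = 5)
  cp <- crossprod(pc$scores)
  off <- cp[upper.tri(cp)]
  expect_true(all(abs(off) < 1e-8 * nrow(pc$scores)))
  expect_true(all(diff(pc$explained) <= 1e-12))
  expect_true(all(pc$explained >= 0))
  expect_lte(sum(pc$explained), 1 + 1e-8)
})

test_that("PC1 separates strongly diverged populations", {
  cfg <- sim_config(n_pop1 = 80, n_pop2 = 80, n_snps = 400,
                    n_chromosomes = 4, drift_generations = 22,
                    n_qtl = 20, seed = 21)
  pool <- generate_founder_haplotypes(cfg)
  div <- diverge_populations(pool, cfg)
  expect_gt(div$realized_fst, 0.06)
  pc <- pca_genotypes(div$genotypes, k = 2)
  lab <- as.numeric(div$genotypes$meta$origin == "POP2")
  expect_gt(abs(cor(pc$scores[, 1], lab)), 0.9)
})

test_that("eigen-of-GRM and SVD-of-Z give the same principal subspace", {
  d <- subset_genotypes(small_cohort()$genotypes, samples = 1:60, snps = 1:200)
  p1 <- pca_genotypes(d, k = 3, standardize = "vanraden")
  # independent route: SVD of the VanRaden-scaled centered dosage matrix
  X <- d$dosage
  storage.mode(X) <- "double"
  p <- allele_freqs(d)
  keep <- p > 0 & p < 1
  Z <- sweep(X[, keep], 2, 2 * p[keep], "-") /
    sqrt(2 * sum(p[keep] * (1 - p[keep])))
  sv <- svd(Z, nu = 3, nv = 0)
  scores_svd <- sv$u %*% diag(sv$d[1:3])
  # same subspace up to sign/rotation: canonical correlations ~ 1
  cc <- svd(crossprod(qr.Q(qr(p1$scores)), qr.Q(qr(scores_svd))))$d
  expect_true(all(cc > 1 - 1e-6))
  expect_equal(p1$eigenvalues, sv$d[1:3]^2, tolerance = 1e-8)
})

test_that("PC ranking splits into deterministic near-equal groups", {
  co <- small_cohort()
  pc <- pca_genotypes(co$genotypes, k = 2)
  # remainder rule: larger blocks first
  fake <- pc
  fake$scores <- pc$scores[1:5, , drop = FALSE]
  fake$sample_ids <- pc$sample_ids[1:5]
  s5 <- split_by_pc(fake, 1, 2)
  expect_equal(as.vector(table(s5$group)), c(3, 2))
  # 1,178 UK-like samples -> 589 + 589
  expect_equal(jointgp:::block_sizes(1178, 2), c(589, 589))
  # sign flip permutes labels, not the partition
  s1 <- split_by_pc(pc, 1, 2)
  flipped <- pc; flipped$scores[, 1] <- -flipped$scores[, 1]
  s2 <- split_by_pc(flipped, 1, 2)
  g1 <- split(s1$id, s1$group)
  g2 <- split(s2$id, s2$group)
  expect_setequal(g1$G1, g2$G2)
  expect_setequal(g1$G2, g2$G1)
})

test_that("duplicated population has F_ST near zero", {
  co <- small_cohort()
  pop1 <- which(co$genotypes$meta$origin == "POP1")
  d <- subset_genotypes(co$genotypes, samples = pop1)
  labels <- rep(c("X", "Y"), length.out = length(pop1))
  # X and Y are interleaved copies of one population
  f <- fst(d, labels)
  expect_lt(abs(f$mean_fst), 0.005)
})

test_that("a fixed allele-frequency difference gives theta = 1", {
  # one SNP fixed for opposite alleles, n = 50 per population
  d <- toy_genotypes(cbind(fix = c(rep(0, 50), rep(2, 50)),
                           other = rep(c(0, 1, 2, 1), 25)),
                     pos = c(100, 200),
                     origin = rep(c("POP1", "POP2"), each = 50))
  f <- fst(d)
  expect_equal(f$per_snp$theta[1], 1, tolerance = 1e-6)
})

test_that("ratio-of-averages mean matches an independent textbook oracle", {
  co <- small_cohort()
  d <- subset_genotypes(co$genotypes, snps = 1:20)
  f <- fst(d)
  # independent implementation of Weir & Cockerham (1984), scalar loop
  oracle_components <- function(x1, x2) {
    n1 <- sum(!is.na(x1)); n2 <- sum(!is.na(x2)); r <- 2
    p1 <- mean(x1, na.rm = TRUE) / 2; p2 <- mean(x2, na.rm = TRUE) / 2
    h1 <- mean(x1 == 1, na.rm = TRUE); h2 <- mean(x2 == 1, na.rm = TRUE)
    nbar <- (n1 + n2) / 2
    nc <- (n1 + n2 - (n1^2 + n2^2) / (n1 + n2)) / (r - 1)
    pbar <- (n1 * p1 + n2 * p2) / (n1 + n2)
    hbar <- (n1 * h1 + n2 * h2) / (n1 + n2)
    s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
    a <- (nbar / nc) * (s2 - (pbar * (1 - pbar) - s2 / 2 - hbar / 4) / (nbar - 1))
    b <- (nbar / (nbar - 1)) *
      (pbar * (1 - pbar) - s2 / 2 - (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    c(a = a, d = a + b + cc)
  }
  i1 <- which(d$meta$origin == "POP1"); i2 <- which(d$meta$origin == "POP2")
  comp <- sapply(seq_len(20), function(j) {
    oracle_components(d$dosage[i1, j], d$dosage[i2, j])
  })
  keep <- !is.na(f$per_snp$a)
  expect_equal(f$mean_fst, sum(comp["a", keep]) / sum(comp["d", keep]),
               tolerance = 1e-10)
  expect_equal(unname(f$per_snp$theta[keep]),
               unname(comp["a", keep] / comp["d", keep]), tolerance = 1e-10)
})

test_that("fst requires exactly two non-empty populations", {
  d <- toy_genotypes(matrix(c(0, 1, 2, 1), 2, 2), pos = c(100, 200))
  expect_error(fst(d, c("A", "A")), "exactly two populations")
})

test_that("LD consistency is 1 against itself and orientation-invariant", {
  co <- small_cohort()
  pop1 <- subset_genotypes(co$genotypes,
                           samples = which(co$genotypes$meta$origin == "POP1"))
  self <- ld_consistency(pop1, pop1, window_bp = 5e6)
  expect_equal(self$correlation, 1, tolerance = 1e-12)
  expect_gt(self$n_pairs, 50)
  # flip allele coding of one SNP consistently in one input
  flipped <- pop1
  j <- which(pmin(allele_freqs(pop1), 1 - allele_freqs(pop1)) > 0.2)[1]
  flipped$dosage[, j] <- 2L - flipped$dosage[, j]
  tmp <- flipped$map$a1[j]
  flipped$map$a1[j] <- flipped$map$a2[j]; flipped$map$a2[j] <- tmp
  out <- ld_consistency(pop1, flipped, window_bp = 5e6)
  expect_equal(out$correlation, 1, tolerance = 1e-12)
})

test_that("independently generated panels show no LD consistency", {
  mk <- function(seed) {
    set.seed(seed)
    n <- 150; m <- 150
    # independent SNPs: no LD at all, so paired r values are noise
    dos <- sapply(runif(m, 0.2, 0.8), function(p) rbinom(n, 2, p))
    toy_genotypes(dos, pos = seq_len(m) * 1000)
  }
  out <- ld_consistency(mk(1), mk(2), window_bp = 2e5)
  expect_gt(out$n_pairs, 1000)
  expect_lt(abs(out$correlation), 0.1)
})

test_that("LD consistency drops as sister populations drift apart", {
  cons_at <- function(gens, s) {
    cfg <- sim_config(n_pop1 = 100, n_pop2 = 100, n_snps = 300,
                      n_chromosomes = 3, drift_generations = gens, seed = s)
    div <- diverge_populations(generate_founder_haplotypes(cfg), cfg)
    a <- subset_genotypes(div$genotypes,
                          samples = which(div$genotypes$meta$origin == "POP1"))
    b <- subset_genotypes(div$genotypes,
                          samples = which(div$genotypes$meta$origin == "POP2"))
    ld_consistency(a, b, window_bp = 2e6)$correlation
  }
  seeds <- 1:6
  near <- sapply(seeds, function(s) cons_at(2, s))
  far <- sapply(seeds, function(s) cons_at(30, s))
  expect_gt(median(near), median(far))
})

test_that("GRM text formats round-trip", {
  g <- small_grm()
  td <- withr::local_tempdir()
  write_grm(g, file.path(td, "k"))
  back <- read_grm(file.path(td, "k"), "full")
  expect_equal(unname(back$K), unname(g$K), tolerance = 1e-10)
  expect_equal(rownames(back$K), rownames(g$K))
  # GCTA-style lower-triangle text
  n <- 4
  K4 <- g$K[1:n, 1:n]
  idx <- which(lower.tri(K4, diag = TRUE), arr.ind = TRUE)
  df <- data.frame(i = idx[, 1], j = idx[, 2], m = 100,
                   v = K4[idx])
  df <- df[df$i >= df$j, ]
  write.table(df, file.path(td, "g4.grm.txt"), sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  writeLines(rownames(K4), file.path(td, "g4.grm.id"))
  b4 <- read_grm(file.path(td, "g4"), "gcta")
  expect_equal(unname(b4$K), unname(K4), tolerance = 1e-10)
})
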