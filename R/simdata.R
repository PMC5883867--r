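#' Simulation configuration for a two-population cohort
#'
#' Defines the study conditions emulated by the generator: two Labrador-like
#' populations of unequal size diverged by a few generations of drift
#' (inter-population F_ST near 0.03), a dense SNP panel with
#' distance-decaying LD, and a polygenic liability expressed as Norberg
#' angles on left and right hips that are converted to 0-6 ordinal scores.
#'
#' Defaults are desk-scale: 600 + 150 individuals and 2,000 SNPs on 38
#' autosome-like chromosomes stand in for the full-size cohorts (1,179 +
#' 242 dogs, ~100k SNPs). `effective_size = 100` with
#' `drift_generations = 6` targets F_ST = 1 - (1 - 1/(2 Ne))^g ~ 0.03.
#' `target_h2` is the heritability of the mean left/right phenotype on the
#' underlying angle (liability) scale (default 0.3, the trait's moderate
#' heritability); the ordinal score phenotype carries slightly less genetic
#' signal because the 0-6 binning coarsens the angle;
#' `lr_correlation` is the left/right score correlation (0.6).
#' `angle_mean`/`angle_sd` (104, 9 degrees) place the bulk of dogs at
#' scores of 2 or below.
#'
#' @param n_pop1,n_pop2 Individuals per population.
#' @param n_snps Total SNPs across the genome.
#' @param n_chromosomes Number of chromosomes; SNPs are split as evenly as
#'   possible (remainder to the first chromosomes).
#' @param chrom_length_bp Chromosome length in bp.
#' @param n_qtl Number of causal markers sampled from the panel.
#' @param target_h2 Heritability of the mean-score phenotype, in `[0, 1]`.
#' @param lr_correlation Target correlation between left and right scores.
#' @param drift_generations Wright-Fisher generations of independent drift
#'   per population after the split.
#' @param effective_size Haploid pool is `2 * effective_size` per population.
#' @param n_founders Distinct founder haplotypes seeding the ancestral pool.
#' @param founder_generations Random-mating generations used to expand the
#'   founders into the ancestral pool (builds distance-decaying LD).
#' @param recomb_rate_per_bp Crossover rate per bp per meiosis (default
#'   1e-8, i.e. 1 cM/Mb).
#' @param sex_effect,origin_effect Fixed effects in score units added to
#'   the liability for males and for population 2 respectively.
#' @param angle_mean,angle_sd Mean and sd of the simulated Norberg angle
#'   (degrees).
#' @param hidden_qtl If `TRUE`, QTL are dropped from the marker panel after
#'   trait simulation (imperfect LD between markers and causal variants).
#' @param seed Integer seed; identical configs give bit-identical cohorts.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_pop1 = 600, n_pop2 = 150, n_snps = 2000,
                       n_chromosomes = 38, chrom_length_bp = 6e7,
                       n_qtl = 100, target_h2 = 0.3, lr_correlation = 0.6,
                       drift_generations = 6, effective_size = 100,
                       n_founders = 30, founder_generations = 20,
                       recomb_rate_per_bp = 1e-8,
                       sex_effect = 0.1, origin_effect = 0.1,
                       angle_mean = 104, angle_sd = 9,
                       hidden_qtl = FALSE, seed = 1) {
  cfg <- as.list(environment())
  counts <- c(n_pop1 = n_pop1, n_pop2 = n_pop2, n_snps = n_snps,
              n_chromosomes = n_chromosomes, chrom_length_bp = chrom_length_bp,
              effective_size = effective_size, n_founders = n_founders)
  if (any(counts <= 0)) stop("all counts must be positive")
  if (target_h2 < 0 || target_h2 > 1) stop("target_h2 must be in [0, 1]")
  if (n_qtl > n_snps) stop("n_qtl cannot exceed n_snps")
  if (drift_generations < 0) stop("drift_generations must be >= 0")
  structure(cfg, class = "sim_config")
}

# deterministic sub-stream seeds derived from the top-level seed
substream_seed <- function(seed, label) {
  (seed * 1000003L + sum(utf8ToInt(label)) * 7919L) %% .Machine$integer.max
}

#' Generate an ancestral haplotype pool with distance-decaying LD
#'
#' A small set of founder haplotypes (random alleles at frequencies drawn
#' per SNP) is expanded through several generations of random mating with
#' recombination at a uniform per-bp crossover rate. Founder linkage makes
#' nearby SNPs co-inherited, so adjacent-SNP LD exceeds long-range LD, and
#' decays with distance as crossovers accumulate.
#'
#' @param config A [sim_config()].
#' @return A list: `haplotypes` (2*effective_size x n_snps 0/1 matrix) and
#'   `map` (marker map tibble).
#' @export
generate_founder_haplotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(substream_seed(config$seed, "founders"))
  m <- config$n_snps
  map <- make_marker_map(m, config$n_chromosomes, config$chrom_length_bp)
  # founder alleles: per-SNP frequency away from the boundaries so drift
  # rarely fixes everything
  p0 <- stats::runif(m, 0.1, 0.9)
  H <- matrix(stats::rbinom(config$n_founders * m, 1, rep(p0, each = config$n_founders)),
              nrow = config$n_founders, ncol = m)
  pool_size <- 2L * config$effective_size
  # expand founders to the pool, then mate-with-recombination for a few
  # generations to break up long-range founder linkage
  H <- H[sample.int(config$n_founders, pool_size, replace = TRUE), , drop = FALSE]
  for (g in seq_len(config$founder_generations)) {
    H <- next_generation(H, map, config$recomb_rate_per_bp, pool_size)
  }
  pbar <- colMeans(H)
  if (all(pbar %in% c(0, 1))) {
    stop("founder pool is monomorphic everywhere; increase n_founders")
  }
  list(haplotypes = H, map = map)
}

make_marker_map <- function(m, n_chr, chr_len) {
  per_chr <- rep(m %/% n_chr, n_chr)
  rem <- m %% n_chr
  if (rem > 0) per_chr[seq_len(rem)] <- per_chr[seq_len(rem)] + 1L
  chr <- rep(seq_len(n_chr), per_chr)
  pos <- unlist(lapply(per_chr, function(k) {
    if (k == 0) return(integer(0))
    sort(sample.int(chr_len, k))
  }))
  tibble::tibble(snp = sprintf("snp%05d", seq_len(m)),
                 chr = as.character(chr), pos = as.numeric(pos),
                 a1 = "A", a2 = "B")
}

# one Wright-Fisher generation: each offspring haplotype is a recombinant
# mosaic of two haplotypes drawn with replacement from the parent pool.
# Crossovers form a Poisson process at rate_per_bp along each chromosome;
# chromosomes assort independently (random phase per chromosome). For
# speed, SNPs are laid on a concatenated genome coordinate and each
# offspring draws a single crossover process over the total map length.
next_generation <- function(H, map, rate_per_bp, out_size) {
  m <- ncol(H)
  gc <- genome_coords(map)
  out <- matrix(0L, nrow = out_size, ncol = m)
  n_par <- nrow(H)
  for (i in seq_len(out_size)) {
    pa <- sample.int(n_par, 2, replace = TRUE)
    n_x <- stats::rpois(1, rate_per_bp * gc$total_len)
    phase <- sample(0:1, gc$n_chr, replace = TRUE)
    seg <- if (n_x == 0) 0L else {
      findInterval(gc$gpos, sort(stats::runif(n_x, 0, gc$total_len)))
    }
    use1 <- (seg + phase[gc$chr_index]) %% 2L == 0L
    out[i, ] <- ifelse(use1, H[pa[1], ], H[pa[2], ])
  }
  out
}

# concatenated genome coordinates for a marker map (memo per call site)
genome_coords <- function(map) {
  chr_f <- factor(map$chr, levels = unique(map$chr))
  chr_index <- as.integer(chr_f)
  n_chr <- nlevels(chr_f)
  # per-chromosome span and cumulative offset
  spans <- tapply(map$pos, chr_f, max)
  offsets <- c(0, cumsum(as.numeric(spans)))[seq_len(n_chr)]
  gpos <- map$pos + offsets[chr_index]
  list(gpos = gpos, chr_index = chr_index, n_chr = n_chr,
       total_len = offsets[n_chr] + as.numeric(spans[n_chr]))
}

#' Split an ancestral pool into two drifting populations
#'
#' Each population starts from an independent resampling of the ancestral
#' pool and undergoes `drift_generations` of Wright-Fisher binomial drift
#' (pool of `2 * effective_size` haplotypes re-paired with recombination
#' each generation). Expected divergence is
#' `F_ST ~ 1 - (1 - 1/(2 Ne))^g`, which the defaults tune to ~0.03.
#' Finally `n_pop1`/`n_pop2` diploid individuals are formed by pairing
#' haplotypes drawn from each population's terminal pool.
#'
#' @param pool Output of [generate_founder_haplotypes()].
#' @param config A [sim_config()].
#' @return A list: `genotypes` (a [genotype_dataset()] with origin labels
#'   `POP1`/`POP2`), `realized_fst` (Weir-Cockerham mean).
#' @export
diverge_populations <- function(pool, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(substream_seed(config$seed, "drift"))
  map <- pool$map
  pool_size <- 2L * config$effective_size
  pops <- lapply(1:2, function(k) {
    H <- pool$haplotypes[sample.int(nrow(pool$haplotypes), pool_size,
                                    replace = TRUE), , drop = FALSE]
    for (g in seq_len(config$drift_generations)) {
      H <- next_generation(H, map, config$recomb_rate_per_bp, pool_size)
    }
    H
  })
  n_ind <- c(config$n_pop1, config$n_pop2)
  dosage_blocks <- lapply(1:2, function(k) {
    H <- pops[[k]]
    i1 <- sample.int(nrow(H), n_ind[k], replace = TRUE)
    i2 <- sample.int(nrow(H), n_ind[k], replace = TRUE)
    H[i1, , drop = FALSE] + H[i2, , drop = FALSE]
  })
  dosage <- do.call(rbind, dosage_blocks)
  p <- colMeans(dosage) / 2
  if (all(p %in% c(0, 1))) {
    stop("all SNPs monomorphic after drift; reduce drift_generations or ",
         "increase effective_size")
  }
  ids <- sprintf("ind%04d", seq_len(sum(n_ind)))
  meta <- tibble::tibble(
    id = ids,
    sex = NA_character_,
    origin = rep(c("POP1", "POP2"), n_ind))
  rownames(dosage) <- ids
  colnames(dosage) <- map$snp
  geno <- genotype_dataset(dosage, map, meta)
  realized <- fst(geno)$mean_fst
  list(genotypes = geno, realized_fst = realized)
}

#' Simulate the polygenic ordinal hip trait
#'
#' Samples `n_qtl` causal markers with Gaussian effects, builds breeding
#' values `g = Z a`, and generates left/right Norberg angles on a liability
#' scale: larger genetic liability means a smaller angle and hence a larger
#' (worse) ordinal score. Residual variance is partitioned into a
#' dog-level and a side-level part so that (i) the mean left/right score
#' has heritability `target_h2` and (ii) the left/right score correlation
#' matches `lr_correlation`. Sexes are assigned at random; `sex_effect`
#' and `origin_effect` shift the liability in score units.
#'
#' @param geno A [genotype_dataset()] (e.g. from [diverge_populations()]).
#' @param config A [sim_config()].
#' @param scale A [score_scale()] used for the angle-to-score conversion.
#' @return A list: `phenotypes` (tibble: id, sex, origin, angle_left,
#'   angle_right, score_left, score_right, score_mean, true_bv),
#'   `qtl` (tibble: snp, effect), `realized_h2` (share of the mean-score
#'   liability variance that is genetic), and `genotypes` (the input, with
#'   sexes filled in and QTL dropped when `hidden_qtl`).
#' @export
simulate_trait <- function(geno, config, scale = score_scale()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(substream_seed(config$seed, "trait"))
  n <- n_samples(geno)
  h2 <- config$target_h2
  if (h2 == 1 && config$n_qtl == 0) {
    stop("target_h2 = 1 with no QTL: no genetic variance available")
  }

  sex <- sample(c("M", "F"), n, replace = TRUE)
  geno$meta$sex <- sex

  qtl_idx <- sort(sample.int(n_snps(geno), config$n_qtl))
  a <- stats::rnorm(config$n_qtl)
  Zq <- geno$dosage[, qtl_idx, drop = FALSE]
  storage.mode(Zq) <- "double"
  g_raw <- as.numeric(Zq %*% a)
  vg_raw <- stats::var(g_raw)

  # per-side liability variance partition (score units), with the mean
  # score's genetic share = h2 and corr(left, right) = lr_correlation:
  #   v_shared = v_g (rho / h2eff - 1),  v_side = v_g (1 - rho) / h2eff * 2
  # derived from rho = (v_g + v_sh) / v_tot, h2 = v_g / (v_g + v_sh + v_sd/2)
  rho <- config$lr_correlation
  g <- if (vg_raw > 0) (g_raw - mean(g_raw)) / sqrt(vg_raw) else rep(0, n)
  genetic <- h2 > 0 && vg_raw > 0
  if (genetic) {
    v_g <- 1
    # solve: v_g/(v_g + v_sh + v_sd/2) = h2 ; (v_g + v_sh)/(v_g+v_sh+v_sd) = rho
    # => v_g + v_sh = rho * T, v_sd = (1-rho) T, T = 2 v_g / (h2 (1+rho));
    # feasible when rho >= h2 / (2 - h2)
    Tt <- 2 * v_g / (h2 * (1 + rho))
    v_sh <- rho * Tt - v_g
    v_sd <- (1 - rho) * Tt
    if (v_sh < 0) {
      stop("infeasible (target_h2, lr_correlation): need lr_correlation >= ",
           round(h2 / (2 - h2), 3))
    }
  } else {
    # no genetic signal: unit total per-side variance, split by rho
    v_g <- 0
    v_sh <- rho
    v_sd <- 1 - rho
  }

  e_shared <- stats::rnorm(n, 0, sqrt(v_sh))
  e_left <- stats::rnorm(n, 0, sqrt(v_sd))
  e_right <- stats::rnorm(n, 0, sqrt(v_sd))
  fixed <- ifelse(sex == "M", config$sex_effect, 0) +
    ifelse(geno$meta$origin == "POP2", config$origin_effect, 0)

  g_in <- if (genetic) g else 0
  liab_left <- fixed + g_in + e_shared + e_left
  liab_right <- fixed + g_in + e_shared + e_right
  # map liability (score units) to angle: higher liability -> smaller angle
  sd_liab <- stats::sd(c(liab_left, liab_right))
  deg_per_unit <- if (sd_liab > 0) config$angle_sd / sd_liab else 1
  center <- mean(c(liab_left, liab_right))
  angle_left <- config$angle_mean - deg_per_unit * (liab_left - center)
  angle_right <- config$angle_mean - deg_per_unit * (liab_right - center)

  score_left <- angle_to_score(angle_left, scale)
  score_right <- angle_to_score(angle_right, scale)
  score_mean <- (score_left + score_right) / 2

  liab_mean <- (liab_left + liab_right) / 2
  realized_h2 <- if (genetic) stats::var(g) / stats::var(liab_mean) else 0

  phen <- tibble::tibble(
    id = geno$meta$id, sex = sex, origin = geno$meta$origin,
    angle_left = angle_left, angle_right = angle_right,
    angle_mean = (angle_left + angle_right) / 2,
    score_left = score_left, score_right = score_right,
    score_mean = score_mean,
    true_bv = g)
  qtl <- tibble::tibble(snp = geno$map$snp[qtl_idx], effect = a)
  if (isTRUE(config$hidden_qtl)) {
    keep <- setdiff(seq_len(n_snps(geno)), qtl_idx)
    geno <- subset_genotypes(geno, snps = keep)
  }
  list(phenotypes = phen, qtl = qtl, realized_h2 = realized_h2,
       genotypes = geno)
}

#' Simulate a complete two-population cohort
#'
#' Convenience wrapper chaining [generate_founder_haplotypes()],
#' [diverge_populations()] and [simulate_trait()].
#'
#' @param config A [sim_config()].
#' @param scale A [score_scale()].
#' @return A `simulated_cohort` list: `genotypes`, `phenotypes`, `qtl`,
#'   `realized_h2`, `realized_fst`, `config`.
#' @export
simulate_cohort <- function(config = sim_config(), scale = score_scale()) {
  pool <- generate_founder_haplotypes(config)
  div <- diverge_populations(pool, config)
  tr <- simulate_trait(div$genotypes, config, scale)
  structure(list(genotypes = tr$genotypes, phenotypes = tr$phenotypes,
                 qtl = tr$qtl, realized_h2 = tr$realized_h2,
                 realized_fst = div$realized_fst, config = config),
            class = "simulated_cohort")
}

#' @export
print.simulated_cohort <- function(x, ...) {
  cat("<simulated_cohort> ", n_samples(x$genotypes), " dogs x ",
      n_snps(x$genotypes), " SNPs; F_ST = ", round(x$realized_fst, 4),
      "; mean-score h2 (realized, liability) = ", round(x$realized_h2, 3),
      "\n", sep = "")
  invisible(x)
}

#' Write a simulated cohort to disk
#'
#' Genotypes via [write_genotypes()] and phenotypes as a TSV with columns
#' id, sex, origin, angle_left, angle_right, score_left, score_right,
#' score_mean, true_bv.
#'
#' @param cohort A `simulated_cohort`.
#' @param dir Output directory (created if needed).
#' @param format Genotype format passed to [write_genotypes()].
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, format = c("tsv", "plink-bed")) {
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (format == "tsv") {
    write_genotypes(cohort$genotypes, file.path(dir, "genotypes.tsv"), "tsv")
  } else {
    write_genotypes(cohort$genotypes, file.path(dir, "genotypes"), "plink-bed")
  }
  readr::write_tsv(cohort$phenotypes, file.path(dir, "phenotypes.tsv"))
  readr::write_tsv(cohort$qtl, file.path(dir, "qtl.tsv"))
  invisible(dir)
}
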