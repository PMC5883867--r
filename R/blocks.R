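#' Estimate haplotype blocks (simplified Gabriel algorithm)
#'
#' For every intra-chromosome SNP pair within `max_span_bp`, two-SNP
#' haplotype frequencies are estimated from unphased genotypes by EM, and
#' D' with a confidence interval is obtained by profiling the likelihood
#' over D' with the allele frequencies held at their estimates. Pairs are
#' classified as strong LD (CI within `strong_low`..1 and upper bound at
#' least `strong_high`), strong evidence of recombination (upper bound
#' below `recomb_high`), or uninformative. Candidate spans are then
#' accepted greedily, longest first (ties to the leftmost start), whenever
#' at least `min_strong_frac` of their informative pairs are strong LD and
#' the outermost pair is informative-strong; accepted spans never overlap.
#'
#' @param d A [genotype_dataset()] with a sorted marker map and >= 10
#'   samples.
#' @param max_span_bp Maximum block span (default 200 kb).
#' @param strong_low,strong_high D' CI thresholds for strong LD
#'   (defaults 0.70 and 0.98).
#' @param recomb_high Upper-CI threshold for strong recombination
#'   (default 0.90).
#' @param min_strong_frac Minimum fraction of informative pairs in strong
#'   LD (default 0.95).
#' @param min_maf Pairs involving SNPs below this MAF are uninformative
#'   (default 0.05).
#' @return A `haplotype_blocks` object: tibble with columns `chr`,
#'   `start_bp`, `end_bp`, `span_bp`, `n_snps`, `snps` (list-column of
#'   member SNP ids); attribute `total_span_bp`.
#' @export
estimate_blocks <- function(d, max_span_bp = 2e5,
                            strong_low = 0.70, strong_high = 0.98,
                            recomb_high = 0.90, min_strong_frac = 0.95,
                            min_maf = 0.05) {
  if (n_samples(d) < 10) stop("need at least 10 samples for block estimation")
  if (is.unsorted(order(d$map$chr, d$map$pos))) stop("marker map unsorted")
  maf <- pmin(allele_freqs(d), 1 - allele_freqs(d))

  blocks <- purrr::map_dfr(split(seq_len(n_snps(d)), d$map$chr), function(idx) {
    if (length(idx) < 2) return(NULL)
    chr_blocks(d, idx, maf, max_span_bp, strong_low, strong_high,
               recomb_high, min_strong_frac, min_maf)
  })
  if (nrow(blocks) > 0) {
    blocks <- dplyr::arrange(blocks, .data$chr, .data$start_bp)
  } else {
    blocks <- tibble::tibble(chr = character(), start_bp = numeric(),
                             end_bp = numeric(), span_bp = numeric(),
                             n_snps = integer(), snps = list())
  }
  structure(blocks, class = c("haplotype_blocks", class(blocks)),
            total_span_bp = sum(blocks$span_bp))
}

chr_blocks <- function(d, idx, maf, max_span_bp, strong_low, strong_high,
                       recomb_high, min_strong_frac, min_maf) {
  pos <- d$map$pos[idx]
  m <- length(idx)
  # classify pairs: 1 strong LD, -1 strong recombination, 0 uninformative
  cls <- matrix(0L, m, m)
  for (i in seq_len(m - 1)) {
    for (j in (i + 1):m) {
      if (pos[j] - pos[i] > max_span_bp) break
      if (maf[idx[i]] < min_maf || maf[idx[j]] < min_maf) next
      ci <- dprime_ci(d$dosage[, idx[i]], d$dosage[, idx[j]])
      if (is.null(ci)) next
      if (ci$low >= strong_low && ci$high >= strong_high) {
        cls[i, j] <- 1L
      } else if (ci$high < recomb_high) {
        cls[i, j] <- -1L
      }
    }
  }
  # candidate spans, longest first, leftmost tie-break
  cand <- list()
  for (i in seq_len(m - 1)) {
    for (j in (i + 1):m) {
      if (pos[j] - pos[i] > max_span_bp) break
      if (cls[i, j] != 1L) next  # outermost pair must be strong
      sub <- cls[i:j, i:j, drop = FALSE]
      vals <- sub[upper.tri(sub)]
      informative <- sum(vals != 0L)
      if (informative == 0) next
      if (sum(vals == 1L) / informative >= min_strong_frac) {
        cand[[length(cand) + 1]] <- c(i = i, j = j, span = pos[j] - pos[i])
      }
    }
  }
  if (length(cand) == 0) return(NULL)
  cand <- do.call(rbind, cand)
  cand <- cand[order(-cand[, "span"], cand[, "i"]), , drop = FALSE]
  taken <- rep(FALSE, m)
  out <- list()
  for (r in seq_len(nrow(cand))) {
    i <- cand[r, "i"]; j <- cand[r, "j"]
    if (any(taken[i:j])) next
    taken[i:j] <- TRUE
    out[[length(out) + 1]] <- tibble::tibble(
      chr = d$map$chr[idx[i]], start_bp = pos[i], end_bp = pos[j],
      span_bp = pos[j] - pos[i], n_snps = j - i + 1L,
      snps = list(d$map$snp[idx[i:j]]))
  }
  dplyr::bind_rows(out)
}

# Two-SNP EM haplotype frequencies from unphased genotypes, then a profile
# of the multinomial likelihood over D' (allele freqs fixed at their
# estimates) to get a confidence interval on |D'|.
# Returns NULL when uninformative (missing-heavy or monomorphic).
dprime_ci <- function(g1, g2, grid_n = 101, conf = 0.90) {
  ok <- !is.na(g1) & !is.na(g2)
  g1 <- g1[ok]; g2 <- g2[ok]
  n <- length(g1)
  if (n < 10) return(NULL)
  p <- mean(g1) / 2; q <- mean(g2) / 2
  if (p <= 0 || p >= 1 || q <= 0 || q >= 1) return(NULL)
  counts <- table(factor(g1, 0:2), factor(g2, 0:2))
  f11 <- em_hap_freq(g1, g2, p, q)
  D <- f11 - p * q
  dmax <- if (D >= 0) min(p * (1 - q), (1 - p) * q) else min(p * q, (1 - p) * (1 - q))
  if (dmax <= 0) return(NULL)
  # profile likelihood over |D'| in [0, 1], sign fixed at the estimate
  sgn <- if (D >= 0) 1 else -1
  dp_grid <- seq(0, 1, length.out = grid_n)
  ll <- vapply(dp_grid, function(dp) {
    hap_loglik(counts, p, q, p * q + sgn * dp * dmax)
  }, numeric(1))
  w <- exp(ll - max(ll))
  w <- w / sum(w)
  cw <- cumsum(w)
  alpha <- (1 - conf) / 2
  low <- dp_grid[which(cw >= alpha)[1]]
  high <- dp_grid[which(cw >= 1 - alpha)[1]]
  list(dprime = abs(D) / dmax, low = low, high = high)
}

# EM for the frequency of the 1-1 haplotype. Every genotype class except
# the double heterozygote carries a determined number of 1-1 haplotype
# copies, namely max(0, g1 + g2 - 2); the double heterozygote is cis
# (11/00) or trans (10/01) with posterior odds f11*f00 : f10*f01.
em_hap_freq <- function(g1, g2, p, q, max_iter = 100, tol = 1e-10) {
  n2 <- 2 * length(g1)
  dh <- g1 == 1 & g2 == 1
  n_dh <- sum(dh)
  base <- sum(pmax(0, g1[!dh] + g2[!dh] - 2))
  lo <- max(0, p + q - 1) + 1e-12
  hi <- min(p, q) - 1e-12
  f11 <- min(max(p * q, lo), hi)
  for (it in seq_len(max_iter)) {
    f10 <- p - f11; f01 <- q - f11; f00 <- 1 - p - q + f11
    cis <- f11 * f00
    trans <- f10 * f01
    frac <- if (cis + trans > 0) cis / (cis + trans) else 0.5
    new_f11 <- min(max((base + n_dh * frac) / n2, lo), hi)
    if (abs(new_f11 - f11) < tol) { f11 <- new_f11; break }
    f11 <- new_f11
  }
  f11
}

# multinomial log-likelihood of the 3x3 genotype-class counts given
# haplotype frequencies implied by (p, q, f11), assuming random pairing
hap_loglik <- function(counts, p, q, f11) {
  f11 <- max(min(f11, min(p, q) - 1e-12), max(0, p + q - 1) + 1e-12)
  f <- c(`00` = 1 - p - q + f11, `01` = q - f11, `10` = p - f11, `11` = f11)
  if (any(f <= 0)) return(-Inf)
  probs <- matrix(0, 3, 3)
  hap_a <- c(0L, 0L, 1L, 1L)  # allele at locus 1 per haplotype class
  hap_b <- c(0L, 1L, 0L, 1L)  # allele at locus 2
  for (h1 in 1:4) {
    for (h2 in 1:4) {
      i <- hap_a[h1] + hap_a[h2] + 1L
      j <- hap_b[h1] + hap_b[h2] + 1L
      probs[i, j] <- probs[i, j] + f[h1] * f[h2]
    }
  }
  sum(counts * log(pmax(probs, 1e-300)))
}

#' @export
print.haplotype_blocks <- function(x, ...) {
  cat("<haplotype_blocks> ", nrow(x), " block(s), total span ",
      attr(x, "total_span_bp"), " bp\n", sep = "")
  NextMethod()
}

#' Write haplotype blocks in PLINK `.blocks.det`-style TSV
#'
#' Columns: chr, bp1, bp2, kb, nsnps, snps (pipe-separated member ids).
#'
#' @param blocks A `haplotype_blocks` object.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_blocks_det <- function(blocks, path) {
  df <- data.frame(
    CHR = blocks$chr, BP1 = blocks$start_bp, BP2 = blocks$end_bp,
    KB = round(blocks$span_bp / 1000, 3), NSNPS = blocks$n_snps,
    SNPS = vapply(blocks$snps, paste, character(1), collapse = "|"))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Genome coverage of a SNP subset by haplotype blocks
#'
#' The fraction of the total haplotype-block span (denominator: the summed
#' span of all blocks, not chromosome length) covered by blocks containing
#' at least one subset SNP.
#'
#' @param blocks A `haplotype_blocks` object.
#' @param subset A `snp_subset` or character vector of SNP ids.
#' @return A list: `genome` (scalar fraction) and `per_chr` (tibble:
#'   chr, covered_bp, total_bp, fraction).
#' @export
coverage_fraction <- function(blocks, subset) {
  if (nrow(blocks) == 0) stop("no haplotype blocks: coverage undefined")
  ids <- if (inherits(subset, "snp_subset")) subset$snp_ids else as.character(subset)
  hit <- vapply(blocks$snps, function(s) any(s %in% ids), logical(1))
  per_chr <- tibble::tibble(chr = blocks$chr, span = blocks$span_bp,
                            hit = hit) |>
    dplyr::group_by(.data$chr) |>
    dplyr::summarise(covered_bp = sum(.data$span[.data$hit]),
                     total_bp = sum(.data$span),
                     fraction = .data$covered_bp / .data$total_bp)
  list(genome = sum(blocks$span_bp[hit]) / sum(blocks$span_bp),
       per_chr = per_chr)
}
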