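#' Cross-population consistency of linkage disequilibrium
#'
#' For every intra-chromosome SNP pair within `window_bp` whose minor
#' allele frequency exceeds `maf_floor` in both populations, the signed
#' genotype-dosage correlation r is computed in each population with a
#' shared reference allele. The statistic returned is the Pearson
#' correlation across pairs of the two populations' r values: values near
#' 1 mean the populations share marker-phase structure, which is what
#' makes marker effects portable between them.
#'
#' @param a,b [genotype_dataset()] objects on a shared SNP set (matched by
#'   SNP id; allele orientation is harmonized internally by flipping b's
#'   dosages where allele labels are swapped).
#' @param window_bp Maximum pair distance (default 1e6).
#' @param maf_floor Minimum MAF required in both populations (default 0.05).
#' @param max_pairs Optional cap on pairs (closest first) to bound work.
#' @return A list with `correlation` (scalar), `n_pairs`, and `pairs`
#'   (tibble: snp_i, snp_j, dist_bp, r_a, r_b).
#' @export
ld_consistency <- function(a, b, window_bp = 1e6, maf_floor = 0.05,
                           max_pairs = NULL) {
  stopifnot(window_bp > 0)
  shared <- intersect(a$map$snp, b$map$snp)
  if (length(shared) < 2) stop("need at least 2 shared SNPs")
  a <- subset_genotypes(a, snps = shared)
  b <- subset_genotypes(b, snps = shared)
  # harmonize orientation: flip b where allele labels are swapped
  swap <- a$map$a1 == b$map$a2 & a$map$a2 == b$map$a1 & a$map$a1 != b$map$a1
  if (any(swap)) b$dosage[, swap] <- 2L - b$dosage[, swap]

  pa <- allele_freqs(a); pb <- allele_freqs(b)
  ok <- pmin(pa, 1 - pa) > maf_floor & pmin(pb, 1 - pb) > maf_floor
  if (sum(ok) < 2) stop("no qualifying SNP pairs (MAF floor too strict)")
  a <- subset_genotypes(a, snps = which(ok))
  b <- subset_genotypes(b, snps = which(ok))

  pairs <- purrr::map_dfr(split(seq_len(nrow(a$map)), a$map$chr), function(idx) {
    if (length(idx) < 2) return(NULL)
    pos <- a$map$pos[idx]
    ii <- jj <- integer(0)
    for (s in seq_len(length(idx) - 1)) {
      t <- which(pos > pos[s] & pos - pos[s] <= window_bp)
      t <- t[t > s]
      ii <- c(ii, rep(s, length(t))); jj <- c(jj, t)
    }
    tibble::tibble(i = idx[ii], j = idx[jj],
                   dist_bp = a$map$pos[idx[jj]] - a$map$pos[idx[ii]])
  })
  if (nrow(pairs) == 0) stop("no qualifying SNP pairs within window")
  if (!is.null(max_pairs) && nrow(pairs) > max_pairs) {
    pairs <- dplyr::slice_min(pairs, .data$dist_bp, n = max_pairs,
                              with_ties = FALSE)
  }
  Ca <- suppressWarnings(stats::cor(a$dosage, use = "pairwise.complete.obs"))
  Cb <- suppressWarnings(stats::cor(b$dosage, use = "pairwise.complete.obs"))
  r_a <- Ca[cbind(pairs$i, pairs$j)]
  r_b <- Cb[cbind(pairs$i, pairs$j)]
  keep <- is.finite(r_a) & is.finite(r_b)
  pairs <- pairs[keep, ]
  r_a <- r_a[keep]; r_b <- r_b[keep]
  if (nrow(pairs) < 2) stop("no qualifying SNP pairs with defined LD")
  list(correlation = stats::cor(r_a, r_b),
       n_pairs = nrow(pairs),
       pairs = tibble::tibble(snp_i = a$map$snp[pairs$i],
                              snp_j = a$map$snp[pairs$j],
                              dist_bp = pairs$dist_bp, r_a = r_a, r_b = r_b))
}
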