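#' Weir-Cockerham F_ST between two populations
#'
#' Per-SNP Weir & Cockerham (1984) theta for two populations, aggregated
#' genome-wide as the ratio of averages `sum(a) / sum(a + b + c)` (the
#' PLINK convention). SNPs where the variance components are undefined
#' (e.g. monomorphic across both populations, or with fewer than two
#' non-missing calls in a population) are excluded from the mean.
#'
#' @param d A [genotype_dataset()].
#' @param pop_labels Vector of population labels, one per sample (GRM
#'   order) or named by sample id; exactly two distinct labels required.
#'   Defaults to `d$meta$origin`.
#' @return A list with `per_snp` (tibble: snp, chr, pos, theta, a, babc)
#'   and `mean_fst` (ratio-of-averages estimate).
#' @export
fst <- function(d, pop_labels = NULL) {
  if (is.null(pop_labels)) pop_labels <- d$meta$origin
  if (!is.null(names(pop_labels))) pop_labels <- pop_labels[d$meta$id]
  pops <- unique(stats::na.omit(pop_labels))
  if (length(pops) != 2) stop("exactly two populations required, got ", length(pops))
  i1 <- which(pop_labels == pops[1]); i2 <- which(pop_labels == pops[2])
  if (length(i1) == 0 || length(i2) == 0) stop("one population is empty")

  X1 <- d$dosage[i1, , drop = FALSE]
  X2 <- d$dosage[i2, , drop = FALSE]
  comp <- wc_components(X1, X2)
  denom <- comp$a + comp$b + comp$c
  ok <- comp$defined & is.finite(denom) & denom != 0
  theta <- ifelse(ok, comp$a / denom, NA_real_)
  per_snp <- tibble::tibble(snp = d$map$snp, chr = d$map$chr, pos = d$map$pos,
                            theta = unname(theta),
                            a = unname(ifelse(comp$defined, comp$a, NA)),
                            babc = unname(ifelse(comp$defined, denom, NA)))
  use <- comp$defined & is.finite(denom)
  mean_fst <- sum(comp$a[use]) / sum(denom[use])
  list(per_snp = per_snp, mean_fst = mean_fst)
}

# Weir & Cockerham (1984) a, b, c for r = 2 populations, vectorized by SNP.
wc_components <- function(X1, X2) {
  n1 <- colSums(!is.na(X1)); n2 <- colSums(!is.na(X2))
  p1 <- colMeans(X1, na.rm = TRUE) / 2
  p2 <- colMeans(X2, na.rm = TRUE) / 2
  h1 <- colMeans(X1 == 1, na.rm = TRUE)
  h2 <- colMeans(X2 == 1, na.rm = TRUE)
  r <- 2
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (1 / (nbar - 1)) * (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - ((r - 1) / r) * s2 - ((2 * nbar - 1) / (4 * nbar)) * hbar)
  cc <- hbar / 2
  defined <- n1 >= 2 & n2 >= 2 & nbar > 1 & is.finite(nc) & nc > 0 &
    (pbar > 0 & pbar < 1 | hbar > 0)
  list(a = a, b = b, c = cc, defined = defined)
}
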