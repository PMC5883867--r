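#' Principal component analysis of genotypes
#'
#' Eigen-decomposition of a variance-standardized genomic relationship
#' matrix. Two standardizations are exposed: `"plink"` divides each
#' centered dosage by `sqrt(2p(1-p))` before forming `XX'/m` (the PLINK
#' `--pca` convention, default here for population stratification) and
#' `"vanraden"` uses the Method 1 global scaling of [compute_grm()]. Both
#' span the same leading subspace on full-rank data.
#'
#' @param d A [genotype_dataset()].
#' @param k Number of components to return (`k < n`).
#' @param standardize `"plink"` or `"vanraden"`.
#' @return An object of class `pca_result`: list with `scores` (n x k,
#'   eigenvector times sqrt(eigenvalue)), `explained` (fraction of total
#'   variance per component), `eigenvalues`, `sample_ids`.
#' @export
pca_genotypes <- function(d, k = 10, standardize = c("plink", "vanraden")) {
  standardize <- match.arg(standardize)
  n <- n_samples(d)
  stopifnot(k >= 1)
  if (k >= n) stop("k must be smaller than the number of samples")
  K <- if (standardize == "plink") {
    X <- d$dosage
    storage.mode(X) <- "double"
    p <- allele_freqs(d)
    poly <- p > 0 & p < 1
    X <- X[, poly, drop = FALSE]; p <- p[poly]
    if (anyNA(X)) {
      na_idx <- which(is.na(X), arr.ind = TRUE)
      X[na_idx] <- 2 * p[na_idx[, 2]]
    }
    Z <- sweep(X, 2, 2 * p, "-")
    Z <- sweep(Z, 2, sqrt(2 * p * (1 - p)), "/")
    tcrossprod(Z) / ncol(Z)
  } else {
    compute_grm(d, ridge = 0)$K
  }
  eig <- eigen(K, symmetric = TRUE)
  pos <- eig$values > 1e-10 * max(eig$values)
  rank <- sum(pos)
  if (k > rank) {
    warning("k = ", k, " exceeds rank ", rank, "; truncating")
    k <- rank
  }
  lam <- eig$values[seq_len(k)]
  scores <- sweep(eig$vectors[, seq_len(k), drop = FALSE], 2, sqrt(lam), "*")
  rownames(scores) <- d$meta$id
  colnames(scores) <- paste0("PC", seq_len(k))
  structure(list(scores = scores,
                 explained = lam / sum(eig$values[eig$values > 0]),
                 eigenvalues = lam,
                 sample_ids = d$meta$id),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat("<pca_result> ", length(x$sample_ids), " samples, ",
      ncol(x$scores), " components; explained: ",
      paste(sprintf("%.1f%%", 100 * utils::head(x$explained, 4)),
            collapse = ", "), " ...\n", sep = "")
  invisible(x)
}

#' Tidy PCA scores
#' @param x A `pca_result`.
#' @param ... Unused.
#' @return Tibble with `id` and one column per component.
#' @export
tidy.pca_result <- function(x, ...) {
  dplyr::bind_cols(tibble::tibble(id = x$sample_ids),
                   tibble::as_tibble(x$scores))
}

#' Partition samples by ranking along a principal component
#'
#' Ranks samples by their score on one component and cuts the ranking into
#' contiguous blocks of near-equal size (larger blocks first). Ties are
#' broken deterministically by sample id, so the partition is invariant to
#' the arbitrary sign of the eigenvector (group labels may swap).
#'
#' @param pca A `pca_result`.
#' @param which_pc Component to rank by (default 1).
#' @param groups Number of groups (>= 2).
#' @return Tibble with columns `id`, `pc_score`, `group` (factor
#'   `"G1"..."Gk"` in rank order).
#' @export
split_by_pc <- function(pca, which_pc = 1, groups = 2) {
  stopifnot(groups >= 2)
  sc <- pca$scores[, which_pc]
  ord <- order(sc, pca$sample_ids)
  n <- length(sc)
  sizes <- block_sizes(n, groups)
  grp <- rep(paste0("G", seq_len(groups)), times = sizes)
  tibble::tibble(id = pca$sample_ids[ord], pc_score = sc[ord],
                 group = factor(grp, levels = paste0("G", seq_len(groups))))
}

# n split into k near-equal blocks, larger blocks first
block_sizes <- function(n, k) {
  base <- n %/% k
  extra <- n %% k
  c(rep(base + 1L, extra), rep(base, k - extra))
}
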