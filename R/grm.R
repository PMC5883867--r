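#' Genomic relationship matrix (VanRaden Method 1)
#'
#' Computes `G = ZZ' / (2 * sum(p * (1 - p)))` where `Z` is the dosage
#' matrix centered by twice the allele frequency per SNP. Missing dosages
#' are mean-filled (i.e. set to `2p`) before centering, so they contribute
#' zero to relationships. A small ridge can be added to the diagonal to
#' guarantee invertibility.
#'
#' @param d A [genotype_dataset()].
#' @param freqs Optional allele-1 frequencies (named by SNP or in map
#'   order). Defaults to in-sample frequencies. Supplying frequencies from
#'   a larger reference (e.g. the full joint cohort before fold subsetting)
#'   keeps the centering consistent across cross-validation folds.
#' @param ridge Value added to the diagonal after scaling (default 0).
#' @param snps Optional SNP ids/indices restricting the marker panel.
#' @return An object of class `grm`: list with elements `K` (n x n matrix,
#'   dimnames = sample ids), `freqs`, `snp_ids`, `ridge`, `denom`.
#' @export
compute_grm <- function(d, freqs = NULL, ridge = 0, snps = NULL) {
  if (!is.null(snps)) {
    idx <- if (is.character(snps)) match(snps, d$map$snp) else as.integer(snps)
    if (anyNA(idx)) stop("unknown SNP id(s) in `snps`")
    d <- subset_genotypes(d, snps = sort(idx))  # genome order
  }
  X <- d$dosage
  storage.mode(X) <- "double"
  p <- if (is.null(freqs)) {
    allele_freqs(d)
  } else if (!is.null(names(freqs))) {
    fq <- freqs[colnames(X)]
    if (anyNA(fq)) stop("supplied freqs missing for some SNPs")
    fq
  } else {
    if (length(freqs) != ncol(X)) stop("freqs length != number of SNPs")
    freqs
  }
  poly <- p > 0 & p < 1
  if (sum(poly) < 2) stop("fewer than 2 polymorphic SNPs; GRM undefined")
  X <- X[, poly, drop = FALSE]
  p <- p[poly]
  # mean-fill missing, then center by 2p
  if (anyNA(X)) {
    na_idx <- which(is.na(X), arr.ind = TRUE)
    X[na_idx] <- 2 * p[na_idx[, 2]]
  }
  Z <- sweep(X, 2, 2 * p, "-")
  denom <- 2 * sum(p * (1 - p))
  K <- tcrossprod(Z) / denom
  if (ridge != 0) diag(K) <- diag(K) + ridge
  dimnames(K) <- list(d$meta$id, d$meta$id)
  structure(list(K = K, freqs = p, snp_ids = colnames(X),
                 ridge = ridge, denom = denom),
            class = "grm")
}

#' @export
print.grm <- function(x, ...) {
  cat("<grm> ", nrow(x$K), " x ", ncol(x$K), " from ", length(x$snp_ids),
      " SNPs; ridge = ", x$ridge, "\n", sep = "")
  invisible(x)
}

#' Write a GRM as full symmetric TSV plus an id list
#'
#' `<path>.grm.tsv` holds the full matrix (no header, tab-separated) and
#' `<path>.grm.id` one sample id per line.
#'
#' @param g A `grm`.
#' @param path Output prefix.
#' @return `path`, invisibly.
#' @export
write_grm <- function(g, path) {
  utils::write.table(g$K, paste0(path, ".grm.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  writeLines(rownames(g$K), paste0(path, ".grm.id"))
  invisible(path)
}

#' Read a GRM from full-matrix TSV or GCTA-style lower-triangle text
#'
#' Accepts the format written by [write_grm()] (`format = "full"`), or a
#' GCTA-style text file with one `i j n_snps value` row per lower-triangle
#' element, 1-based indices (`format = "gcta"`), with ids in
#' `<path>.grm.id`.
#'
#' @param path Path prefix.
#' @param format `"full"` or `"gcta"`.
#' @return A `grm` (frequencies unknown; `ridge` recorded as `NA`).
#' @export
read_grm <- function(path, format = c("full", "gcta")) {
  format <- match.arg(format)
  ids <- readLines(paste0(path, ".grm.id"))
  n <- length(ids)
  K <- if (format == "full") {
    m <- as.matrix(utils::read.table(paste0(path, ".grm.tsv"), sep = "\t"))
    if (!all(dim(m) == n)) stop("GRM dimensions do not match the id list")
    unname(m)
  } else {
    df <- utils::read.table(paste0(path, ".grm.txt"))
    m <- matrix(0, n, n)
    m[cbind(df[[1]], df[[2]])] <- df[[4]]
    m[cbind(df[[2]], df[[1]])] <- df[[4]]
    m
  }
  dimnames(K) <- list(ids, ids)
  structure(list(K = K, freqs = NULL, snp_ids = NULL, ridge = NA_real_,
                 denom = NA_real_), class = "grm")
}

#' Summarize GRM diagonal and off-diagonal blocks by group
#'
#' Mean and sd of diagonal elements within each group, and of off-diagonal
#' elements within and between groups (the within-group off-diagonal
#' excludes the diagonal). Mirrors the standard description of relatedness
#' within and between two merged populations.
#'
#' @param g A `grm`.
#' @param groups Factor/character vector of group labels, one per sample
#'   (in GRM order), or a named vector matched by sample id.
#' @return A tibble with columns `group1`, `group2`, `part`
#'   (`"diagonal"` or `"off_diagonal"`), `mean`, `sd`, `n_pairs`.
#' @export
grm_group_summary <- function(g, groups) {
  K <- g$K
  n <- nrow(K)
  if (!is.null(names(groups))) groups <- groups[rownames(K)]
  if (length(groups) != n) stop("groups must have one label per sample")
  groups <- as.character(groups)
  labs <- unique(groups)
  out <- list()
  for (a in labs) {
    ia <- which(groups == a)
    dvals <- diag(K)[ia]
    out[[length(out) + 1]] <- tibble::tibble(
      group1 = a, group2 = a, part = "diagonal",
      mean = mean(dvals), sd = stats::sd(dvals), n_pairs = length(ia))
    # within-group off-diagonal (upper triangle)
    if (length(ia) >= 2) {
      block <- K[ia, ia, drop = FALSE]
      ov <- block[upper.tri(block)]
      out[[length(out) + 1]] <- tibble::tibble(
        group1 = a, group2 = a, part = "off_diagonal",
        mean = mean(ov), sd = stats::sd(ov), n_pairs = length(ov))
    } else {
      out[[length(out) + 1]] <- tibble::tibble(
        group1 = a, group2 = a, part = "off_diagonal",
        mean = NA_real_, sd = NA_real_, n_pairs = 0L)
    }
  }
  if (length(labs) >= 2) {
    for (i in seq_len(length(labs) - 1)) {
      for (j in (i + 1):length(labs)) {
        ia <- which(groups == labs[i]); ib <- which(groups == labs[j])
        block <- K[ia, ib, drop = FALSE]
        out[[length(out) + 1]] <- tibble::tibble(
          group1 = labs[i], group2 = labs[j], part = "off_diagonal",
          mean = mean(block), sd = stats::sd(as.vector(block)),
          n_pairs = length(block))
      }
    }
  }
  dplyr::bind_rows(out)
}
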