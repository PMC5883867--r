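#' Single-SNP linear mixed-model association scan
#'
#' Tests each SNP in `y = W alpha + x beta + u + e` with
#' `u ~ N(0, G sigma_g2)`. The polygenic background is handled by
#' eigendecomposing the training-block GRM once and rotating `y`, `W`
#' and every SNP column into the eigenbasis, where the model collapses to
#' weighted least squares with per-observation weights
#' `1 / (lambda d_j + 1)` at the variance ratio
#' `lambda = sigma_g2 / sigma_e2`. By default `lambda` is fixed at the
#' null-model (no-SNP) REML estimate for all SNPs; ranking SNPs for
#' preselection is insensitive to per-SNP re-estimation at this scale,
#' but `per_snp_lambda = TRUE` re-optimizes the ratio under each
#' alternative model. Significance uses the Wald statistic
#' `(beta / se)^2` against chi-squared with 1 df.
#'
#' @param phenotypes Tibble with `id`, `sex`, `origin` and `response`.
#' @param geno A [genotype_dataset()] containing at least the phenotyped
#'   individuals.
#' @param grm A `grm` covering the phenotyped individuals (ridge already
#'   applied as desired).
#' @param response Phenotype column (default `"score_mean"`).
#' @param lambda Optional fixed variance ratio; if `NULL`, estimated by
#'   [fit_aireml()] on the null model.
#' @param per_snp_lambda Re-optimize lambda per SNP (slower; default FALSE).
#' @return A `gwas_result` tibble: `snp`, `chr`, `pos`, `beta`, `se`,
#'   `wald`, `p`, `rank` (ascending p; ties broken by genome order).
#'   SNPs constant in the sample are returned with `NA` statistics and are
#'   excluded from ranking. Attribute `lambda` records the ratio used.
#' @export
fit_lmm_gwas <- function(phenotypes, geno, grm, response = "score_mean",
                         lambda = NULL, per_snp_lambda = FALSE) {
  phen <- tibble::as_tibble(phenotypes)
  ids <- phen$id
  geno <- subset_genotypes(geno, samples = ids)
  K <- grm$K[ids, ids, drop = FALSE]
  y <- phen[[response]]
  W <- prepare_design(design_matrix(phen), length(y))

  if (is.null(lambda)) {
    fit0 <- fit_aireml(y, W, K)
    lambda <- fit0$sigma_g2 / fit0$sigma_e2
  }

  eig <- eigen(K, symmetric = TRUE)
  U <- eig$vectors
  d <- pmax(eig$values, 0)
  wts <- 1 / (lambda * d + 1)
  yr <- crossprod(U, y)
  Wr <- crossprod(U, W)
  X <- geno$dosage
  storage.mode(X) <- "double"
  if (anyNA(X)) {
    p <- allele_freqs(geno)
    na_idx <- which(is.na(X), arr.ind = TRUE)
    X[na_idx] <- 2 * p[na_idx[, 2]]
  }
  mono <- apply(X, 2, function(col) stats::var(col) == 0)
  Xr <- crossprod(U, X)

  n <- length(y); kq <- ncol(Wr)
  # residualize y and each SNP against W under the weights, then 1-df GLS
  sw <- sqrt(wts)
  Wt <- Wr * sw
  yt <- yr * sw
  Xt <- Xr * sw
  qrW <- qr(Wt)
  y_res <- stats::resid(stats::lm.fit(Wt, yt))
  X_res <- qr.resid(qrW, Xt)

  if (per_snp_lambda) {
    res <- per_snp_lambda_scan(yr, Wr, Xr, d, mono)
    beta <- res$beta; se <- res$se
  } else {
    sxx <- colSums(X_res^2)
    sxy <- as.numeric(crossprod(X_res, y_res))
    beta <- sxy / sxx
    syy <- sum(y_res^2)
    rss <- syy - beta^2 * sxx
    df <- n - kq - 1
    sigma2 <- rss / df
    se <- sqrt(sigma2 / sxx)
  }
  beta[mono] <- NA_real_; se[mono] <- NA_real_
  wald <- (beta / se)^2
  pval <- stats::pchisq(wald, df = 1, lower.tail = FALSE)
  pval[!is.na(pval) & pval == 0] <- .Machine$double.xmin

  out <- tibble::tibble(snp = geno$map$snp, chr = geno$map$chr,
                        pos = geno$map$pos, beta = unname(beta),
                        se = unname(se), wald = unname(wald),
                        p = unname(pval))
  ord <- order(out$p, seq_len(nrow(out)), na.last = TRUE)
  rank <- integer(nrow(out)); rank[ord] <- seq_len(nrow(out))
  rank[is.na(out$p)] <- NA_integer_
  out$rank <- rank
  attr(out, "lambda") <- lambda
  class(out) <- c("gwas_result", class(out))
  out
}

# grid+refine profile of the ratio under each alternative model (ML on the
# rotated scale); used only when per_snp_lambda = TRUE
per_snp_lambda_scan <- function(yr, Wr, Xr, d, mono) {
  n <- length(yr)
  grid <- exp(seq(log(1e-4), log(1e4), length.out = 25))
  m <- ncol(Xr)
  beta <- se <- rep(NA_real_, m)
  for (j in seq_len(m)) {
    if (mono[j]) next
    best <- NULL
    for (lam in grid) {
      wts <- 1 / (lam * d + 1)
      sw <- sqrt(wts)
      Xfull <- cbind(Wr, Xr[, j]) * sw
      fitj <- stats::lm.fit(Xfull, yr * sw)
      rss <- sum(fitj$residuals^2)
      ll <- -0.5 * (n * log(rss / n) - sum(log(wts)))
      if (is.null(best) || ll > best$ll) {
        kq <- ncol(Xfull)
        sigma2 <- rss / (n - kq)
        xtx_inv <- chol2inv(qr.R(qr(Xfull)))
        best <- list(ll = ll, beta = fitj$coefficients[kq],
                     se = sqrt(sigma2 * xtx_inv[kq, kq]))
      }
    }
    beta[j] <- best$beta; se[j] <- best$se
  }
  list(beta = beta, se = se)
}

#' Select a SNP subset for prediction
#'
#' Either the leading SNPs of a GWAS ranking (`mode = "preselected"`,
#' smallest p first, ties broken by genome order) or a uniform random
#' draw (`mode = "random"`). The subset size is `floor(fraction * m)`.
#'
#' @param x A `gwas_result` (required for `preselected`) or a
#'   [genotype_dataset()] / character vector of SNP ids (for `random`).
#' @param fraction Fraction of the panel in `(0, 1]`.
#' @param mode `"preselected"` or `"random"`.
#' @param seed Seed for random mode.
#' @return A `snp_subset`: list with `snp_ids`, `mode`, `fraction`, `seed`.
#' @export
select_subset <- function(x, fraction, mode = c("preselected", "random"),
                          seed = 1) {
  mode <- match.arg(mode)
  stopifnot(fraction > 0, fraction <= 1)
  panel <- if (inherits(x, "gwas_result")) x$snp
           else if (inherits(x, "genotype_dataset")) x$map$snp
           else as.character(x)
  n_take <- floor(fraction * length(panel))
  if (n_take < 1) stop("fraction ", fraction, " selects zero SNPs")
  ids <- if (mode == "preselected") {
    if (!inherits(x, "gwas_result")) stop("preselected mode needs a gwas_result")
    # unranked SNPs (untestable in the training set) go last, genome order,
    # so fraction 1 always returns the full panel
    ord <- order(x$rank, seq_len(nrow(x)), na.last = TRUE)
    x$snp[ord][seq_len(n_take)]
  } else {
    set.seed(seed)
    sample(panel, n_take)
  }
  structure(list(snp_ids = ids, mode = mode, fraction = fraction,
                 seed = if (mode == "random") seed else NA_integer_),
            class = "snp_subset")
}

#' @export
print.snp_subset <- function(x, ...) {
  cat("<snp_subset> ", length(x$snp_ids), " SNPs (", x$mode, ", fraction ",
      x$fraction, ")\n", sep = "")
  invisible(x)
}

#' SNP-subset prediction experiment nested in cross-validation
#'
#' For each fold of a k-fold split and each requested fraction: rank SNPs
#' by GWAS run on the training records only (never the validation fold, to
#' avoid leaking association signal into the accuracy), select the subset,
#' rebuild the GRM from the subset alone (joint-cohort allele frequencies
#' restricted to the subset), refit the variance components and predict
#' the validation fold. GWAS effect sizes rank SNPs only; prediction
#' re-estimates all SNP effects jointly through the subset GBLUP. Random
#' subsets are replicated.
#'
#' @param phenotypes Tibble with `id`, `sex`, `origin`, `response`.
#' @param geno A [genotype_dataset()] for the same cohort.
#' @param fractions Numeric vector of panel fractions in `(0, 1]`.
#' @param modes Subset of `c("preselected", "random")`.
#' @param k Folds (default 5).
#' @param random_replicates Replicates per fraction for random mode
#'   (default 20).
#' @param ridge GRM ridge (default 0.01).
#' @param seed Base seed.
#' @param response Phenotype column.
#' @return Tibble: `fraction`, `mode`, `replicate`, `fold`,
#'   `validation_origin`, `rho`, `mse`, `slope`, `h2`, `n_snps`.
#' @export
subset_prediction_experiment <- function(phenotypes, geno,
                                         fractions = c(0.01, 0.05, 0.1, 0.25,
                                                       0.5, 0.75, 1),
                                         modes = c("preselected", "random"),
                                         k = 5, random_replicates = 20,
                                         ridge = 0.01, seed = 1,
                                         response = "score_mean") {
  stopifnot(all(fractions > 0), all(fractions <= 1))
  modes <- match.arg(modes, several.ok = TRUE)
  phen <- tibble::as_tibble(phenotypes)
  joint_freqs <- allele_freqs(geno)
  names(joint_freqs) <- geno$map$snp
  grm_full <- compute_grm(geno, freqs = joint_freqs, ridge = ridge)
  folds <- make_folds(phen, k = k, seed = seed)
  phen_f <- dplyr::left_join(phen, folds[, c("id", "fold")], by = "id")
  origins <- sort(unique(phen$origin))

  rows <- list()
  for (f in seq_len(k)) {
    train <- phen_f |> dplyr::filter(.data$fold != f)
    valid <- phen_f |> dplyr::filter(.data$fold == f)
    gwas <- if ("preselected" %in% modes) {
      fit_lmm_gwas(train, geno, grm_full, response = response)
    } else NULL
    for (fr in fractions) {
      specs <- list()
      if ("preselected" %in% modes) {
        specs[[length(specs) + 1]] <- list(mode = "preselected", rep = 1L,
                                           sub = select_subset(gwas, fr, "preselected"))
      }
      if ("random" %in% modes) {
        n_rep <- if (fr >= 1) 1L else random_replicates
        for (rr in seq_len(n_rep)) {
          specs[[length(specs) + 1]] <- list(
            mode = "random", rep = rr,
            sub = select_subset(geno, fr, "random",
                                seed = seed * 1000 + f * 100 + rr))
        }
      }
      for (sp in specs) {
        res <- subset_fold_eval(train, valid, geno, sp$sub, joint_freqs,
                                ridge, response, origins)
        if (is.null(res) || nrow(res) == 0) next
        res$fraction <- fr; res$mode <- sp$mode
        res$replicate <- sp$rep; res$fold <- f
        res$n_snps <- length(sp$sub$snp_ids)
        rows[[length(rows) + 1]] <- res
      }
    }
  }
  dplyr::bind_rows(rows) |>
    dplyr::select("fraction", "mode", "replicate", "fold",
                  "validation_origin", "rho", "mse", "slope", "h2", "n_snps")
}

subset_fold_eval <- function(train, valid, geno, sub, joint_freqs, ridge,
                             response, origins) {
  grm_sub <- tryCatch(
    compute_grm(geno, freqs = joint_freqs[sub$snp_ids], ridge = ridge,
                snps = sub$snp_ids),
    error = function(e) NULL)
  if (is.null(grm_sub)) return(NULL)
  ft <- fit_fold(train, grm_sub$K, 0, response)  # ridge already in grm_sub
  if (is.null(ft)) return(NULL)
  purrr::map_dfr(origins, function(vo) {
    vsub <- valid |> dplyr::filter(.data$origin == vo)
    if (nrow(vsub) < 3) return(NULL)
    pred <- blup_predict(ft$fit, grm_sub, vsub$id,
                         W_val = design_matrix(vsub, ft$fixed))
    met <- compute_metrics(vsub[[response]], pred$predicted)
    dplyr::bind_cols(tibble::tibble(validation_origin = vo),
                     met[, c("rho", "mse", "slope")],
                     tibble::tibble(h2 = ft$h2))
  })
}
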