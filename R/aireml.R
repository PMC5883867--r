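#' Average-information REML for the univariate GBLUP model
#'
#' Fits `y = W alpha + u + e` with `u ~ N(0, G sigma_g2)` and
#' `e ~ N(0, I sigma_e2)` by restricted maximum likelihood, using
#' Newton-type updates with the average-information (AI) matrix. The
#' restricted log-likelihood is never allowed to decrease: AI steps that
#' would decrease it are halved, and an EM step replaces any AI proposal
#' that leaves the parameter space. Convergence is declared when the
#' variance components, normalized by their sum, change by less than `tol`
#' in maximum absolute difference between iterations.
#'
#' @param y Numeric phenotype vector (e.g. mean Norberg-angle scores).
#' @param W Fixed-effect design matrix (intercept, sex, origin, ...).
#'   Aliased columns (zero variance after the first) are dropped
#'   automatically, so an origin column disappears when the training set is
#'   single-origin.
#' @param G Genomic relationship matrix for the `length(y)` training
#'   samples (a `grm` or a plain matrix); must be positive definite (apply
#'   a diagonal ridge upstream).
#' @param start Optional starting values `c(sigma_g2, sigma_e2)`; default
#'   splits `var(y)` evenly.
#' @param max_iter Maximum AI iterations (default 100).
#' @param tol Convergence tolerance on the normalized components
#'   (default 1e-5).
#' @param verbose Print per-iteration trace?
#' @return An object of class `reml_fit`: variance components
#'   `sigma_g2`/`sigma_e2`, fixed effects `alpha`, BLUPs `u` (training
#'   samples), 2x2 `ai_cov` (inverse AI matrix, the asymptotic sampling
#'   covariance of the components), `loglik`, iteration `trace` tibble,
#'   `converged` and `boundary` flags.
#' @export
fit_aireml <- function(y, W, G, start = NULL, max_iter = 100, tol = 1e-5,
                       verbose = FALSE) {
  if (inherits(G, "grm")) G <- G$K
  y <- as.numeric(y)
  n <- length(y)
  W <- prepare_design(W, n)
  if (nrow(G) != n) stop("G dimension does not match length(y)")

  vy <- stats::var(y)
  if (vy <= 0) stop("phenotype has zero variance")
  floor_val <- 1e-8 * vy
  theta <- if (is.null(start)) c(vy / 2, vy / 2) else as.numeric(start)
  theta <- pmax(theta, floor_val)

  ll_fun <- function(th) reml_loglik(y, W, G, th[1], th[2])
  cur <- ll_fun(theta)
  trace <- list()
  converged <- FALSE
  boundary <- FALSE
  ai_mat <- NULL

  for (it in seq_len(max_iter)) {
    qq <- reml_quadratics(y, W, G, theta[1], theta[2])
    score <- qq$score
    ai_mat <- qq$ai

    # AI proposal; EM fallback when it exits the parameter space
    delta <- tryCatch(solve(ai_mat, score), error = function(e) NULL)
    prop <- if (is.null(delta)) NULL else theta + delta
    used_em <- FALSE
    if (is.null(prop) || any(prop < floor_val)) {
      prop <- em_update(theta, qq, n)
      used_em <- TRUE
    }
    prop <- pmax(prop, floor_val)

    new_ll <- ll_fun(prop)
    halvings <- 0
    while (new_ll$loglik < cur$loglik - 1e-10 && halvings < 20) {
      prop <- (theta + prop) / 2
      prop <- pmax(prop, floor_val)
      new_ll <- ll_fun(prop)
      halvings <- halvings + 1
    }
    if (new_ll$loglik < cur$loglik - 1e-10) {
      # cannot improve: take an EM step, which cannot decrease the likelihood
      prop <- pmax(em_update(theta, qq, n), floor_val)
      new_ll <- ll_fun(prop)
      used_em <- TRUE
    }

    norm_old <- theta / sum(theta)
    norm_new <- prop / sum(prop)
    dnorm <- max(abs(norm_new - norm_old))
    trace[[it]] <- tibble::tibble(iter = it, sigma_g2 = prop[1],
                                  sigma_e2 = prop[2], loglik = new_ll$loglik,
                                  delta_norm = dnorm, em_step = used_em,
                                  halvings = halvings)
    if (verbose) {
      message(sprintf("it %2d: sg2=%.6g se2=%.6g ll=%.6f d=%.2e%s",
                      it, prop[1], prop[2], new_ll$loglik, dnorm,
                      if (used_em) " [EM]" else ""))
    }
    theta <- prop
    cur <- new_ll
    if (dnorm < tol) { converged <- TRUE; break }
  }

  # degenerate data (phenotype in the fixed-effect span): the restricted
  # likelihood is unbounded as the overall variance scale shrinks, while the
  # sum-normalized components stabilize early; detect by testing a scale
  # contraction and clamp to the floor
  if (converged && ll_fun(theta / 10)$loglik > cur$loglik + 1e-6) {
    theta <- c(floor_val, floor_val)
    cur <- ll_fun(theta)
    boundary <- TRUE
  }

  if (any(theta <= floor_val * 1.01)) boundary <- TRUE
  # refresh AI at the solution for the sampling covariance
  qq <- reml_quadratics(y, W, G, theta[1], theta[2])
  ai_mat <- qq$ai
  ai_cov <- tryCatch(solve(ai_mat), error = function(e) {
    matrix(NA_real_, 2, 2)
  })
  if (all(is.finite(ai_mat))) {
    cn <- tryCatch(kappa(ai_mat, exact = TRUE), error = function(e) Inf)
    if (is.finite(cn) && cn > 1e10) boundary <- TRUE
  }
  dimnames(ai_cov) <- list(c("sigma_g2", "sigma_e2"), c("sigma_g2", "sigma_e2"))

  sol <- gblup_solve(y, W, G, theta[1], theta[2])
  structure(list(
    sigma_g2 = theta[1], sigma_e2 = theta[2],
    alpha = sol$alpha, u = sol$u,
    ai_cov = ai_cov, loglik = cur$loglik,
    trace = dplyr::bind_rows(trace),
    converged = converged, boundary = boundary,
    ids = rownames(G), fixed_names = colnames(W),
    n = n, var_floor = floor_val
  ), class = "reml_fit")
}

# drop aliased columns; keep full column rank
prepare_design <- function(W, n) {
  W <- as.matrix(W)
  if (nrow(W) != n) stop("nrow(W) != length(y)")
  if (is.null(colnames(W))) colnames(W) <- paste0("f", seq_len(ncol(W)))
  qr_w <- qr(W)
  if (qr_w$rank < ncol(W)) {
    keep <- qr_w$pivot[seq_len(qr_w$rank)]
    W <- W[, sort(keep), drop = FALSE]
  }
  W
}

# Restricted log-likelihood via Cholesky of V = sg2 G + se2 I:
#   -0.5 [ log|V| + log|W' V^-1 W| + y' P y ]
reml_loglik <- function(y, W, G, sg2, se2) {
  n <- length(y)
  V <- sg2 * G
  diag(V) <- diag(V) + se2
  R <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(R)) return(list(loglik = -Inf))
  logdetV <- 2 * sum(log(diag(R)))
  Vi_y <- backsolve(R, forwardsolve(t(R), y))
  Vi_W <- backsolve(R, forwardsolve(t(R), W))
  WtViW <- crossprod(W, Vi_W)
  Rw <- chol(WtViW)
  logdetWVW <- 2 * sum(log(diag(Rw)))
  alpha <- backsolve(Rw, forwardsolve(t(Rw), crossprod(W, Vi_y)))
  Py <- Vi_y - Vi_W %*% alpha
  yPy <- sum(y * Py)
  list(loglik = -0.5 * (logdetV + logdetWVW + yPy),
       Py = Py, Vi_W = Vi_W, R = R, alpha = alpha)
}

# Score vector and average-information matrix at (sg2, se2).
#   dL/dthi = -0.5 [ tr(P Ai) - y'P Ai P y ],  A1 = G, A2 = I
#   AI_ij   =  0.5  y'P Ai P Aj P y
reml_quadratics <- function(y, W, G, sg2, se2) {
  n <- length(y)
  ll <- reml_loglik(y, W, G, sg2, se2)
  if (!is.finite(ll$loglik)) stop("V numerically singular")
  R <- ll$R
  Py <- ll$Py
  # P M for any M: V^-1 M - V^-1 W (W'V^-1W)^-1 W' V^-1 M
  Vi <- chol2inv(R)
  WtViW_inv <- chol2inv(chol(crossprod(W, ll$Vi_W)))
  P <- Vi - ll$Vi_W %*% WtViW_inv %*% t(ll$Vi_W)
  GPy <- G %*% Py
  PGPy <- P %*% GPy
  PPy <- P %*% Py
  trPG <- sum(P * G)   # tr(P G), both symmetric
  trP <- sum(diag(P))
  score <- c(-0.5 * (trPG - sum(Py * GPy)),
             -0.5 * (trP - sum(Py * Py)))
  ai <- 0.5 * matrix(c(sum(GPy * PGPy), sum(GPy * PPy),
                       sum(GPy * PPy), sum(Py * PPy)), 2, 2)
  list(score = score, ai = ai, loglik = ll$loglik, Py = Py, P = P)
}

# EM-REML step (Harville): thi_new = thi + thi^2 (y'P Ai P y - tr(P Ai)) / n
em_update <- function(theta, qq, n) {
  Py <- qq$Py
  # recover the two quadratic/trace contrasts from the score:
  # score_i = -0.5 (tr(P Ai) - y'P Ai P y)  =>  contrast_i = 2 * score_i
  theta + theta^2 * (2 * qq$score) / n
}

#' Solve the GBLUP mixed model at fixed variance components
#'
#' Returns GLS fixed-effect estimates and BLUPs
#' `u = sigma_g2 G V^-1 (y - W alpha)` for given components.
#'
#' @inheritParams fit_aireml
#' @param sigma_g2,sigma_e2 Variance components.
#' @return List with `alpha` (named) and `u` (named by sample id).
#' @export
gblup_solve <- function(y, W, G, sigma_g2, sigma_e2) {
  if (inherits(G, "grm")) G <- G$K
  W <- prepare_design(W, length(y))
  ll <- reml_loglik(y, W, G, sigma_g2, sigma_e2)
  if (!is.finite(ll$loglik)) stop("V numerically singular")
  u <- as.numeric(sigma_g2 * (G %*% ll$Py))
  names(u) <- rownames(G)
  alpha <- as.numeric(ll$alpha)
  names(alpha) <- colnames(W)
  list(alpha = alpha, u = u)
}

#' @export
print.reml_fit <- function(x, ...) {
  h <- heritability(x)
  cat("<reml_fit> n = ", x$n,
      if (x$converged) " (converged" else " (NOT converged",
      if (x$boundary) ", boundary)" else ")", "\n",
      sprintf("  sigma_g2 = %.4f  sigma_e2 = %.4f  h2 = %.3f (se %.3f)\n",
              x$sigma_g2, x$sigma_e2, h$h2, h$se),
      sep = "")
  invisible(x)
}

#' Tidy a REML fit
#'
#' @param x A `reml_fit`.
#' @param ... Unused.
#' @return Tibble with one row per parameter (`sigma_g2`, `sigma_e2`,
#'   `h2`, fixed effects), columns `term`, `estimate`, `std.error`.
#' @export
tidy.reml_fit <- function(x, ...) {
  h <- heritability(x)
  dplyr::bind_rows(
    tibble::tibble(term = "sigma_g2", estimate = x$sigma_g2,
                   std.error = sqrt(x$ai_cov[1, 1])),
    tibble::tibble(term = "sigma_e2", estimate = x$sigma_e2,
                   std.error = sqrt(x$ai_cov[2, 2])),
    tibble::tibble(term = "h2", estimate = h$h2, std.error = h$se),
    tibble::tibble(term = names(x$alpha), estimate = unname(x$alpha),
                   std.error = NA_real_)
  )
}

#' Glance at a REML fit
#' @param x A `reml_fit`.
#' @param ... Unused.
#' @return One-row tibble: `n`, `sigma_g2`, `sigma_e2`, `h2`, `h2_se`,
#'   `logLik`, `n_iter`, `converged`, `boundary`.
#' @export
glance.reml_fit <- function(x, ...) {
  h <- heritability(x)
  tibble::tibble(n = x$n, sigma_g2 = x$sigma_g2, sigma_e2 = x$sigma_e2,
                 h2 = h$h2, h2_se = h$se, logLik = x$loglik,
                 n_iter = nrow(x$trace), converged = x$converged,
                 boundary = x$boundary)
}

#' Heritability with delta-method standard error
#'
#' `h2 = sigma_g2 / (sigma_g2 + sigma_e2)`, with the standard error
#' propagated from the AI sampling covariance of the components:
#' partials are `d h2 / d sigma_g2 = sigma_e2 / s^2` and
#' `d h2 / d sigma_e2 = -sigma_g2 / s^2` with `s = sigma_g2 + sigma_e2`.
#'
#' @param fit A `reml_fit`, or a list with `sigma_g2`, `sigma_e2` and
#'   2x2 `ai_cov`.
#' @return List with `h2` and `se`.
#' @export
heritability <- function(fit) {
  sg2 <- fit$sigma_g2; se2 <- fit$sigma_e2
  s <- sg2 + se2
  if (s <= 0) stop("total variance is zero; heritability undefined")
  h2 <- sg2 / s
  d <- c(se2 / s^2, -sg2 / s^2)
  v <- fit$ai_cov
  se <- if (is.null(v) || anyNA(v)) NA_real_ else {
    sqrt(drop(t(d) %*% v %*% d))
  }
  list(h2 = h2, se = se)
}

#' Predict genomic values for validation individuals
#'
#' Conditional-expectation GBLUP prediction:
#' `u_val = G[val, train] G[train, train]^{-1} u_train`, plus the fixed
#' effect part for each validation individual's covariates. Equivalent to
#' solving Henderson's equations with validation phenotypes treated as
#' missing (an identity exercised in the tests).
#'
#' @param fit A `reml_fit` from [fit_aireml()] (trained on the training
#'   block of `grm`).
#' @param grm A `grm` (or matrix with dimnames) covering training and
#'   validation individuals.
#' @param validation_ids Character ids of validation individuals; must be
#'   disjoint from the training ids and present in `grm`.
#' @param W_val Optional fixed-effect design rows for the validation
#'   individuals (columns matching `fit$fixed_names`); if omitted, only
#'   the genomic effect `u` is returned as the prediction.
#' @return Tibble with columns `id`, `u` (genomic effect) and `predicted`
#'   (fixed part + u, equal to `u` when `W_val` is omitted).
#' @export
blup_predict <- function(fit, grm, validation_ids, W_val = NULL) {
  K <- if (inherits(grm, "grm")) grm$K else grm
  train_ids <- fit$ids
  if (is.null(train_ids)) stop("fit carries no sample ids")
  if (any(validation_ids %in% train_ids)) {
    stop("validation ids overlap the training set")
  }
  miss <- setdiff(c(validation_ids), rownames(K))
  if (length(miss) > 0) {
    stop("individual(s) absent from the GRM: ",
         paste(utils::head(miss, 3), collapse = ", "))
  }
  Ktt <- K[train_ids, train_ids, drop = FALSE]
  Kvt <- K[validation_ids, train_ids, drop = FALSE]
  u_val <- as.numeric(Kvt %*% solve(Ktt, fit$u))
  fixed <- if (is.null(W_val)) 0 else {
    W_val <- as.matrix(W_val)[, fit$fixed_names, drop = FALSE]
    as.numeric(W_val %*% fit$alpha)
  }
  tibble::tibble(id = validation_ids, u = u_val, predicted = fixed + u_val)
}
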