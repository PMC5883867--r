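#' Assign k-fold cross-validation folds, stratified by origin
#'
#' Within each origin, samples are randomly permuted and cut into `k`
#' near-equal blocks (larger blocks first), so per-origin fold sizes
#' differ by at most one: 1,179 samples give folds of 236/235 and 242
#' give 49/48 at `k = 5`.
#'
#' @param meta Tibble with columns `id` and `origin` (or any data frame
#'   with those columns).
#' @param k Number of folds (default 5).
#' @param seed Integer seed; identical seeds give identical assignments.
#' @return Tibble with columns `id`, `origin`, `fold` (1..k).
#' @export
make_folds <- function(meta, k = 5, seed = 1) {
  stopifnot(k >= 2)
  meta <- tibble::as_tibble(meta)[, c("id", "origin")]
  counts <- table(meta$origin)
  if (any(counts < k)) {
    stop("origin '", names(counts)[which.min(counts)],
         "' has fewer samples than folds")
  }
  set.seed(seed)
  meta |>
    dplyr::group_by(.data$origin) |>
    dplyr::group_modify(function(df, key) {
      n <- nrow(df)
      fold <- rep(seq_len(k), times = block_sizes(n, k))
      df$fold <- fold[sample.int(n)]
      df
    }) |>
    dplyr::ungroup() |>
    dplyr::arrange(match(.data$id, meta$id))
}

#' Prediction-quality metrics
#'
#' Pearson correlation, mean squared error, and the slope of the
#' regression of observed on predicted scores. A slope of 1 means
#' unbiased predictions; slopes above (below) 1 indicate the predictions
#' under- (over-) disperse relative to the phenotypes.
#'
#' @param observed,predicted Numeric vectors of equal length (>= 3).
#' @return One-row tibble: `rho`, `mse`, `slope`, `n_validation`.
#'   `rho` and `slope` are `NA` when `predicted` is constant.
#' @export
compute_metrics <- function(observed, predicted) {
  stopifnot(length(observed) == length(predicted), length(observed) >= 3)
  mse <- mean((observed - predicted)^2)
  vp <- stats::var(predicted)
  if (!is.finite(vp) || vp == 0) {
    return(tibble::tibble(rho = NA_real_, mse = mse, slope = NA_real_,
                          n_validation = length(observed)))
  }
  tibble::tibble(
    rho = stats::cor(observed, predicted),
    mse = mse,
    slope = stats::cov(observed, predicted) / vp,
    n_validation = length(observed))
}

#' Accuracy of selection
#'
#' Converts a prediction correlation to an accuracy of selection by
#' dividing by the square root of heritability: `rho / sqrt(h2)`.
#'
#' @param rho Prediction correlation.
#' @param h2 Heritability in `(0, 1]`.
#' @return `rho / sqrt(h2)`.
#' @export
accuracy_of_selection <- function(rho, h2) {
  if (any(h2 <= 0)) stop("h2 must be positive")
  if (any(h2 > 1)) stop("h2 must be <= 1")
  rho / sqrt(h2)
}

#' Cross-validation configuration
#'
#' @param scheme Training-set design: `"joint"` (both origins' non-held-out
#'   folds), `"pop1-only"`, `"pop2-only"`, or `"balanced-subset"` (equal
#'   random draws per origin per fold).
#' @param k Folds (default 5).
#' @param replicates Number of times the fold split is redrawn (default 10).
#' @param subset_per_origin For `balanced-subset`: number of training dogs
#'   drawn per origin (total across the k-1 training folds).
#' @param ridge GRM diagonal ridge (default 0.01).
#' @param seed Base seed; replicate r uses `seed + r`.
#' @return A `cv_config` list.
#' @export
cv_config <- function(scheme = c("joint", "pop1-only", "pop2-only",
                                 "balanced-subset"),
                      k = 5, replicates = 10, subset_per_origin = NULL,
                      ridge = 0.01, seed = 1) {
  scheme <- match.arg(scheme)
  stopifnot(replicates >= 1, k >= 2)
  if (scheme == "balanced-subset" && is.null(subset_per_origin)) {
    stop("balanced-subset scheme needs subset_per_origin")
  }
  structure(list(scheme = scheme, k = k, replicates = replicates,
                 subset_per_origin = subset_per_origin, ridge = ridge,
                 seed = seed),
            class = "cv_config")
}

#' Run replicated k-fold cross-validation of GBLUP prediction
#'
#' For each replicate and fold: assemble the training set according to the
#' scheme, re-estimate variance components by AI-REML on the training
#' records only, predict the held-out fold of every origin, and score the
#' predictions per validation origin. The GRM is built once from the full
#' cohort (joint allele frequencies) and sub-blocked per fold. Folds whose
#' REML fit does not converge are recorded and excluded from aggregates.
#'
#' @param phenotypes Tibble with `id`, `sex`, `origin` and the phenotype
#'   column named by `response`.
#' @param grm A `grm` covering all phenotyped individuals.
#' @param config A [cv_config()].
#' @param response Phenotype column (default `"score_mean"`).
#' @return A `cv_report`: list with `folds` (tibble: replicate, fold,
#'   scheme, validation_origin, rho, mse, slope, h2, n_train, converged)
#'   and `summary` (per validation origin: mean and min-max range over
#'   replicate means), plus `n_failed`.
#' @export
run_cv <- function(phenotypes, grm, config = cv_config(),
                   response = "score_mean") {
  phen <- tibble::as_tibble(phenotypes)
  stopifnot(response %in% names(phen))
  ids_all <- phen$id
  K <- grm$K
  if (!all(ids_all %in% rownames(K))) stop("phenotyped id(s) absent from GRM")
  origins <- sort(unique(phen$origin))

  rows <- list()
  for (r in seq_len(config$replicates)) {
    rep_seed <- config$seed + r
    folds <- make_folds(phen, k = config$k, seed = rep_seed)
    phen_f <- dplyr::left_join(phen, folds[, c("id", "fold")], by = "id")
    for (f in seq_len(config$k)) {
      train <- cv_training_set(phen_f, f, config, origins,
                               seed = rep_seed * 100 + f)
      valid <- phen_f |> dplyr::filter(.data$fold == f)
      if (nrow(train) < 10) next
      fit <- fit_fold(train, K, config$ridge, response)
      if (is.null(fit)) {
        rows[[length(rows) + 1]] <- tibble::tibble(
          replicate = r, fold = f, scheme = config$scheme,
          validation_origin = NA_character_, rho = NA_real_, mse = NA_real_,
          slope = NA_real_, h2 = NA_real_, n_train = nrow(train),
          converged = FALSE)
        next
      }
      for (vo in origins) {
        vsub <- valid |> dplyr::filter(.data$origin == vo)
        if (nrow(vsub) < 3) next
        pred <- blup_predict(fit$fit, grm, vsub$id,
                             W_val = design_matrix(vsub, fit$fixed))
        met <- compute_metrics(vsub[[response]], pred$predicted)
        rows[[length(rows) + 1]] <- dplyr::bind_cols(
          tibble::tibble(replicate = r, fold = f, scheme = config$scheme,
                         validation_origin = vo),
          met[, c("rho", "mse", "slope")],
          tibble::tibble(h2 = fit$h2, n_train = nrow(train),
                         converged = TRUE))
      }
    }
  }
  folds_tbl <- dplyr::bind_rows(rows)
  if (nrow(folds_tbl) == 0) {
    stop("no fold produced a converged fit; nothing to report")
  }
  new_cv_report(folds_tbl, config)
}

cv_training_set <- function(phen_f, held_out, config, origins, seed) {
  pool <- phen_f |> dplyr::filter(.data$fold != .env$held_out)
  switch(config$scheme,
    "joint" = pool,
    "pop1-only" = pool |> dplyr::filter(.data$origin == origins[1]),
    "pop2-only" = pool |> dplyr::filter(.data$origin == origins[2]),
    "balanced-subset" = {
      set.seed(seed)
      pool |>
        dplyr::group_by(.data$origin) |>
        dplyr::slice_sample(n = config$subset_per_origin) |>
        dplyr::ungroup()
    })
}

# intercept + sex + origin design; origin dropped when single-origin
design_matrix <- function(df, fixed_cols = NULL) {
  W <- cbind(`(Intercept)` = 1,
             sexM = as.numeric(df$sex == "M"),
             origin2 = as.numeric(df$origin != sort(unique(df$origin))[1]))
  if (!is.null(fixed_cols)) {
    # align to training design columns (validation rows need all of them)
    W <- cbind(`(Intercept)` = 1,
               sexM = as.numeric(df$sex == "M"),
               origin2 = as.numeric(df$origin != fixed_cols$ref_origin))
    W <- W[, fixed_cols$names, drop = FALSE]
  }
  W
}

fit_fold <- function(train, K, ridge, response) {
  ref_origin <- sort(unique(train$origin))[1]
  W <- design_matrix(train)
  Kt <- K[train$id, train$id, drop = FALSE]
  diag(Kt) <- diag(Kt) + ridge
  fit <- tryCatch(
    fit_aireml(train[[response]], W, Kt),
    error = function(e) NULL)
  if (is.null(fit) || !fit$converged) return(NULL)
  list(fit = fit, h2 = heritability(fit)$h2,
       fixed = list(names = fit$fixed_names, ref_origin = ref_origin))
}

new_cv_report <- function(folds_tbl, config) {
  ok <- folds_tbl |> dplyr::filter(.data$converged,
                                   !is.na(.data$validation_origin))
  rep_means <- ok |>
    dplyr::group_by(.data$scheme, .data$validation_origin, .data$replicate) |>
    dplyr::summarise(dplyr::across(c("rho", "mse", "slope", "h2"),
                                   ~ mean(.x, na.rm = TRUE)),
                     .groups = "drop")
  summ <- rep_means |>
    dplyr::group_by(.data$scheme, .data$validation_origin) |>
    dplyr::summarise(
      dplyr::across(c("rho", "mse", "slope", "h2"),
                    list(mean = ~ mean(.x, na.rm = TRUE),
                         min = ~ min(.x, na.rm = TRUE),
                         max = ~ max(.x, na.rm = TRUE))),
      n_replicates = dplyr::n(), .groups = "drop")
  structure(list(folds = folds_tbl, summary = summ,
                 n_failed = sum(!folds_tbl$converged), config = config),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat("<cv_report> scheme = ", x$config$scheme, ", ",
      x$config$replicates, " replicate(s) x ", x$config$k, " folds; ",
      x$n_failed, " failed fold-fit(s)\n", sep = "")
  print(x$summary)
  invisible(x)
}

#' Tidy per-fold cross-validation records
#' @param x A `cv_report`.
#' @param ... Unused.
#' @return The per-fold tibble.
#' @export
tidy.cv_report <- function(x, ...) x$folds

#' Glance at a cross-validation report
#' @param x A `cv_report`.
#' @param ... Unused.
#' @return The aggregate summary tibble.
#' @export
glance.cv_report <- function(x, ...) x$summary

#' Train on one PC-defined group, validate on the others
#'
#' No cross-validation: the model is fitted once on the union of the
#' requested training groups and evaluated separately on every excluded
#' group, mirroring prediction between clusters of a principal-component
#' stratification. Small training groups are fitted anyway with a
#' warning, and the fit's boundary/identifiability flag is carried into
#' the output (heritability estimates of 1 with flat likelihoods are the
#' signature of underpowered groups).
#'
#' @param phenotypes Tibble with `id`, `sex`, `origin` and `response`.
#' @param grm A `grm` covering all samples.
#' @param partition Tibble with columns `id`, `group` (e.g. from
#'   [split_by_pc()]).
#' @param train_groups Character vector of group labels to train on.
#' @param ridge GRM ridge (default 0.01).
#' @param response Phenotype column (default `"score_mean"`).
#' @return Tibble with one row per validation group: `train`,
#'   `validation_group`, `rho`, `mse`, `slope`, `h2`, `n_train`, `n_validation`,
#'   `boundary`.
#' @export
pca_group_experiment <- function(phenotypes, grm, partition, train_groups,
                                 ridge = 0.01, response = "score_mean") {
  phen <- tibble::as_tibble(phenotypes)
  part <- tibble::as_tibble(partition)
  phen <- dplyr::inner_join(phen, part[, c("id", "group")], by = "id")
  all_groups <- unique(as.character(phen$group))
  if (!all(train_groups %in% all_groups)) stop("unknown training group(s)")
  val_groups <- setdiff(all_groups, train_groups)
  if (length(val_groups) == 0) {
    stop("training and validation groups must be disjoint: no groups left ",
         "for validation")
  }
  train <- phen |> dplyr::filter(.data$group %in% train_groups)
  if (nrow(train) < 30) {
    warning("training group has fewer than 30 samples; estimates may be ",
            "unidentifiable")
  }
  ref_origin <- sort(unique(train$origin))[1]
  W <- design_matrix(train)
  Kt <- grm$K[train$id, train$id, drop = FALSE]
  diag(Kt) <- diag(Kt) + ridge
  fit <- fit_aireml(train[[response]], W, Kt)
  h2 <- heritability(fit)$h2
  fixed <- list(names = fit$fixed_names, ref_origin = ref_origin)
  purrr::map_dfr(val_groups, function(vg) {
    vsub <- phen |> dplyr::filter(.data$group == vg)
    pred <- blup_predict(fit, grm, vsub$id, W_val = design_matrix(vsub, fixed))
    met <- compute_metrics(vsub[[response]], pred$predicted)
    dplyr::bind_cols(
      tibble::tibble(train = paste(train_groups, collapse = "+"),
                     validation_group = vg),
      met[, c("rho", "mse", "slope")],
      tibble::tibble(h2 = h2, n_train = nrow(train),
                     n_validation = nrow(vsub), boundary = fit$boundary))
  })
}
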