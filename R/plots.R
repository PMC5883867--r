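#' Plot the ordinal score distribution
#'
#' Histogram of mean Norberg-angle scores by origin, in the shape used to
#' describe the cohorts (most dogs at scores of 2 or below).
#'
#' @param phenotypes Tibble with `score_mean` and `origin`.
#' @return A ggplot object.
#' @export
plot_score_distribution <- function(phenotypes) {
  ggplot2::ggplot(phenotypes,
                  ggplot2::aes(x = .data$score_mean, fill = .data$sex)) +
    ggplot2::geom_bar() +
    ggplot2::facet_wrap(ggplot2::vars(.data$origin), scales = "free_y") +
    ggplot2::labs(x = "mean Norberg-angle score", y = "dogs") +
    ggplot2::theme_minimal()
}

#' Autoplot a PCA result
#'
#' Scatter of the first two component scores, optionally colored by a
#' sample grouping (e.g. origin).
#'
#' @param object A `pca_result`.
#' @param groups Optional vector of labels, one per sample.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pca_result <- function(object, groups = NULL, ...) {
  df <- tidy.pca_result(object)
  if (!is.null(groups)) df$group <- groups
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$PC1, y = .data$PC2)) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * object$explained[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * object$explained[2])) +
    ggplot2::theme_minimal()
  if (is.null(groups)) p + ggplot2::geom_point()
  else p + ggplot2::geom_point(ggplot2::aes(colour = .data$group))
}

#' Autoplot a cross-validation report
#'
#' Per-replicate prediction correlations by validation origin, with the
#' replicate mean highlighted.
#'
#' @param object A `cv_report`.
#' @param metric One of `"rho"`, `"mse"`, `"slope"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cv_report <- function(object, metric = c("rho", "mse", "slope"),
                               ...) {
  metric <- match.arg(metric)
  df <- object$folds |> dplyr::filter(.data$converged)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$validation_origin,
                                   y = .data[[metric]])) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.5) +
    ggplot2::labs(x = "validation origin", y = metric,
                  title = paste("scheme:", object$config$scheme)) +
    ggplot2::theme_minimal()
}

#' Plot subset-experiment prediction curves
#'
#' Mean prediction correlation against the fraction of SNPs used, by
#' selection mode (random vs GWAS-preselected) and validation origin.
#'
#' @param subset_results Output of [subset_prediction_experiment()].
#' @return A ggplot object.
#' @export
plot_subset_curves <- function(subset_results) {
  df <- subset_results |>
    dplyr::group_by(.data$fraction, .data$mode, .data$validation_origin) |>
    dplyr::summarise(rho = mean(.data$rho, na.rm = TRUE), .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fraction, y = .data$rho,
                                   colour = .data$mode)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(ggplot2::vars(.data$validation_origin)) +
    ggplot2::labs(x = "fraction of SNPs", y = "prediction correlation") +
    ggplot2::theme_minimal()
}
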