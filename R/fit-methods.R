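## broom-style views and ggplot2 plots for fitted objects.

#' @export
print.cdcn_fit <- function(x, ...) {
  cat("<cdcn_fit> model ", c("I", "II")[x$model],
      ", alpha = ", x$alpha, ", tau = ", x$tau,
      if (x$loocv) ", LOOCV" else ", in-sample", "\n", sep = "")
  cat("  mean per-drug r = ",
      signif(mean(x$per_drug$pearson_r, na.rm = TRUE), 4),
      " over ", nrow(x$per_drug), " drugs (",
      sum(x$observed), " observed pairs)\n", sep = "")
  invisible(x)
}

#' Per-drug metrics of a fitted response prediction
#'
#' @param x A `cdcn_fit` from [loocv_predict()].
#' @param ... Unused.
#' @return A tibble with one row per drug: `drug_id`, `n` (evaluated cell
#'   lines), `pearson_r`, `rmse`, `nrmse`.
#' @exportS3Method generics::tidy
tidy.cdcn_fit <- function(x, ...) {
  x$per_drug
}

#' One-row summary of a fitted response prediction
#'
#' @param x A `cdcn_fit`.
#' @param ... Unused.
#' @return A one-row tibble: model, bandwidths, mean/min/max per-drug
#'   Pearson r, overall RMSE, numbers of pairs evaluated and failed.
#' @exportS3Method generics::glance
glance.cdcn_fit <- function(x, ...) {
  use <- x$observed & !is.na(x$predicted)
  tibble(
    model = c("I", "II")[x$model],
    alpha = x$alpha,
    tau = x$tau,
    loocv = x$loocv,
    mean_r = mean(x$per_drug$pearson_r, na.rm = TRUE),
    min_r = suppressWarnings(min(x$per_drug$pearson_r, na.rm = TRUE)),
    max_r = suppressWarnings(max(x$per_drug$pearson_r, na.rm = TRUE)),
    rmse = sqrt(mean((x$predicted[use] - x$actual[use])^2)),
    n_pairs = sum(use),
    n_failed = x$n_failed
  )
}

#' Long predicted-vs-observed table for a fitted prediction
#'
#' @param x A `cdcn_fit`.
#' @param ... Unused.
#' @return A tibble with `cell_id`, `drug_id`, `observed` (response value)
#'   and `predicted`, restricted to evaluated pairs.
#' @exportS3Method generics::augment
augment.cdcn_fit <- function(x, ...) {
  use <- which(x$observed & !is.na(x$predicted), arr.ind = TRUE)
  tibble(
    cell_id = rownames(x$predicted)[use[, 1]],
    drug_id = colnames(x$predicted)[use[, 2]],
    observed = x$actual[use],
    predicted = x$predicted[use]
  )
}

#' @importFrom generics augment
#' @export
generics::augment

#' Plot per-drug correlations of a fitted prediction
#'
#' @param object A `cdcn_fit`.
#' @param ... Unused.
#' @return A ggplot: per-drug Pearson r between held-out predictions and
#'   observed responses.
#' @exportS3Method ggplot2::autoplot
autoplot.cdcn_fit <- function(object, ...) {
  df <- object$per_drug
  ggplot2::ggplot(df, ggplot2::aes(
    x = stats::reorder(.data$drug_id, .data$pearson_r),
    y = .data$pearson_r)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_flip() +
    ggplot2::labs(
      x = NULL, y = "Pearson r (predicted vs observed)",
      title = paste0("CDCN model ", c("I", "II")[object$model],
                     " (alpha = ", object$alpha,
                     ", tau = ", object$tau, ")")) +
    ggplot2::theme_minimal()
}

#' @export
print.cdcn_grid <- function(x, ...) {
  cat("<cdcn_grid> model ", c("I", "II")[x$model],
      ", step ", x$grid_step, "\n", sep = "")
  cat("  best (alpha, tau) = (", x$alpha, ", ", x$tau, "), SSE = ",
      signif(x$sse, 6), "\n", sep = "")
  invisible(x)
}

#' Full bandwidth error surface of a grid search
#'
#' @param x A `cdcn_grid` from [grid_search()].
#' @param ... Unused.
#' @return A tibble with `alpha`, `tau`, `sse` and `n_ok` (pairs with a
#'   defined prediction) for every grid point.
#' @exportS3Method generics::tidy
tidy.cdcn_grid <- function(x, ...) {
  x$surface
}

#' One-row summary of a grid search
#'
#' @param x A `cdcn_grid`.
#' @param ... Unused.
#' @return A one-row tibble: model, grid step, best bandwidths and SSE.
#' @exportS3Method generics::glance
glance.cdcn_grid <- function(x, ...) {
  tibble(model = c("I", "II")[x$model], grid_step = x$grid_step,
         loocv = x$loocv, alpha = x$alpha, tau = x$tau, sse = x$sse,
         n_grid = nrow(x$surface))
}

#' Plot a bandwidth error surface
#'
#' @param object A `cdcn_grid`.
#' @param ... Unused.
#' @return A ggplot heat map of the LOOCV squared error over the
#'   `(alpha, tau)` grid, with the optimum marked.
#' @exportS3Method ggplot2::autoplot
autoplot.cdcn_grid <- function(object, ...) {
  ggplot2::ggplot(object$surface,
                  ggplot2::aes(x = .data$alpha, y = .data$tau,
                               fill = log10(.data$sse))) +
    ggplot2::geom_tile() +
    ggplot2::annotate("point", x = object$alpha, y = object$tau,
                      colour = "red", shape = 4, size = 3) +
    ggplot2::scale_fill_viridis_c(name = "log10 SSE") +
    ggplot2::labs(x = "alpha (cell-line bandwidth)",
                  y = "tau (drug bandwidth)") +
    ggplot2::theme_minimal()
}

#' Plot the four response-correlation distributions of the generalized
#' observation
#'
#' @param object A tibble from [observation_analysis()].
#' @param ... Unused.
#' @return A ggplot box plot of response correlations for the four
#'   cell-group x drug-group combinations.
#' @exportS3Method ggplot2::autoplot
autoplot.cdcn_observation <- function(object, ...) {
  object$combo <- factor(
    paste(object$cell_group, object$drug_group, sep = " x "),
    levels = c("Hc x Hd", "Hc x Ld", "Lc x Hd", "Lc x Ld"))
  ggplot2::ggplot(object, ggplot2::aes(x = .data$combo, y = .data$r)) +
    ggplot2::geom_boxplot(fill = "grey85") +
    ggplot2::labs(x = NULL, y = "response correlation between cell pairs") +
    ggplot2::theme_minimal()
}
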