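#' Predicted vs chronological age scatter
#'
#' @param age_records Tibble with `age_chron` and a prediction column.
#' @param estimate `"age_pred_raw"` or `"age_pred_norm"`.
#' @return A ggplot object annotated with Pearson r and RMSE.
#' @export
plot_predictions <- function(age_records, estimate = c("age_pred_raw", "age_pred_norm")) {
  estimate <- match.arg(estimate)
  ev <- evaluate_predictions(age_records, "age_chron", estimate)
  ggplot2::ggplot(age_records,
                  ggplot2::aes(x = .data$age_chron, y = .data[[estimate]])) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::labs(
      x = "Chronological age (years)",
      y = if (estimate == "age_pred_raw") "Predicted age (years)"
          else "Normalized predicted age (years)",
      subtitle = sprintf("r = %.2f, RMSE = %.2f years", ev$pearson_r, ev$rmse_years)) +
    ggplot2::theme_minimal()
}

#' Day-by-hour grid of permutation importance
#'
#' Mirrors the classic predictor-strength heat map: one tile per (day, hour)
#' cell, faceted by feature type (hourly max vs hourly variance), filled by
#' %IncMSE.
#'
#' @param importance Output of [rf_importance()].
#' @return A ggplot object.
#' @export
plot_importance_grid <- function(importance) {
  dat <- importance[!is.na(importance$stat), , drop = FALSE]
  dat$stat <- factor(dat$stat, levels = c("max", "var"),
                     labels = c("hourly max", "hourly variance"))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$hour, y = .data$day,
                                    fill = .data$inc_mse_pct)) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(~stat) +
    ggplot2::scale_y_reverse(breaks = 1:7) +
    ggplot2::labs(x = "Hour of day", y = "Day of wear",
                  fill = "%IncMSE") +
    ggplot2::theme_minimal()
}

#' Volcano plot of the drug screen
#'
#' x = median deltaAge shift of users, y = -log10 KS p-value; the dashed
#' lines mark p = 0.05 and p = 0.01. Decelerating candidates sit in the
#' upper-left quadrant.
#'
#' @param drug_screen Output of [screen_drugs()].
#' @param label_top Number of extreme drugs to label (default 5).
#' @return A ggplot object.
#' @export
plot_volcano <- function(drug_screen, label_top = 5) {
  dat <- dplyr::mutate(drug_screen, neg_log_p = -log10(.data$ks_p))
  lab <- utils::head(dat[order(dat$ks_p), , drop = FALSE], label_top)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$median_shift, y = .data$neg_log_p)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = -log10(c(0.05, 0.01)), linetype = "dashed") +
    ggplot2::geom_text(data = lab, ggplot2::aes(label = .data$drug),
                       vjust = -0.6, size = 3) +
    ggplot2::labs(x = "Median deltaAge shift of users (years)",
                  y = "-log10 KS p-value") +
    ggplot2::theme_minimal()
}

#' Nutrient correlation profiles by cluster
#'
#' One line per nutrient across the decade bins, faceted by cluster, showing
#' where in life each nutrient's association with deltaAge peaks.
#'
#' @param nutrient_screen Output of [screen_nutrients()].
#' @param clusters Output of [cluster_nutrients()].
#' @return A ggplot object.
#' @export
plot_cluster_profiles <- function(nutrient_screen, clusters) {
  dat <- dplyr::inner_join(nutrient_screen,
                           clusters[, c("nutrient", "cluster")],
                           by = "nutrient")
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$bin, y = .data$r,
                                    group = .data$nutrient)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::geom_line(alpha = 0.7) +
    ggplot2::facet_wrap(~cluster) +
    ggplot2::labs(x = "Decade of life", y = "Pearson r with deltaAge") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @rdname plot_predictions
#' @param object An `"actage_run"`.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.actage_run <- function(object, ...) {
  plot_predictions(object$age_records, "age_pred_norm")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
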