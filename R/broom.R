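#' Tidy a fitted age model
#'
#' Returns one row per feature with the frozen standardization parameters;
#' if an importance table is supplied it is joined in.
#'
#' @param x An `"actage_rf"` model.
#' @param importance Optional output of [rf_importance()].
#' @param ... Unused.
#' @return A tibble with `feature`, `center`, `scale` (and `inc_mse_pct`).
#' @exportS3Method generics::tidy
tidy.actage_rf <- function(x, importance = NULL, ...) {
  out <- tibble::tibble(feature = x$features,
                        center = unname(x$center),
                        scale = unname(x$scale))
  if (!is.null(importance)) {
    out <- dplyr::left_join(out, importance[, c("feature", "inc_mse_pct")],
                            by = "feature")
  }
  out
}

#' Glance at a fitted age model
#'
#' @param x An `"actage_rf"` model.
#' @param ... Unused.
#' @return One-row tibble: `n_train`, `n_features`, `n_trees`, `mtry`,
#'   `nodesize`, `oob_rmse_years`, `seed`.
#' @exportS3Method generics::glance
glance.actage_rf <- function(x, ...) {
  tibble::tibble(n_train = x$n_train, n_features = length(x$features),
                 n_trees = x$n_trees, mtry = x$mtry, nodesize = x$nodesize,
                 oob_rmse_years = sqrt(x$oob_mse), seed = x$seed)
}

#' Tidy a pipeline run
#'
#' @param x An `"actage_run"`.
#' @param ... Unused.
#' @return The held-out metrics table (`stage`, `pearson_r`, `rmse_years`,
#'   `n`).
#' @exportS3Method generics::tidy
tidy.actage_run <- function(x, ...) {
  x$metrics[, c("stage", "pearson_r", "rmse_years", "n")]
}

#' Glance at a pipeline run
#'
#' @param x An `"actage_run"`.
#' @param ... Unused.
#' @return One-row tibble of the headline numbers of the run.
#' @exportS3Method generics::glance
glance.actage_run <- function(x, ...) {
  s <- x$summary
  tibble::tibble(
    n_input = s$n_input,
    n_retained = s$n_retained,
    pearson_r_raw = s$pearson_r_raw,
    pearson_r_norm = s$pearson_r_norm,
    rmse_raw = s$rmse_raw,
    rmse_norm = s$rmse_norm,
    prop_death_accelerated = s$death_proportions$prop_accelerated %||% NA_real_,
    prop_death_decelerated = s$death_proportions$prop_decelerated %||% NA_real_,
    top_drug = s$top_decelerating_drug$drug %||% NA_character_
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
generics::tidy

#' @export
generics::glance
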