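#' Stratified train/test split
#'
#' Splits participants into disjoint, exhaustive train and test sets,
#' stratified on quantile bins of chronological age so both subsets cover the
#' age range. Deterministic given `seed`.
#'
#' @param data Tibble containing `age_col`.
#' @param train_fraction Fraction assigned to training; must lie in (0, 1).
#' @param seed Integer seed.
#' @param age_col Name of the age column (default `"age_years"`).
#' @param n_bins Number of age-quantile strata (default 5).
#' @return `data` with an added `split` factor column (`"train"`/`"test"`).
#' @export
split_train_test <- function(data, train_fraction = 0.70, seed = 1,
                             age_col = "age_years", n_bins = 5) {
  if (!is.numeric(train_fraction) || train_fraction <= 0 || train_fraction >= 1) {
    rlang::abort("train_fraction must lie strictly between 0 and 1",
                 class = "actage_parameter_error")
  }
  n <- nrow(data)
  if (n < 10) abort_validation("need at least 10 rows to split")
  age <- data[[age_col]]
  if (is.null(age)) abort_schema(sprintf("missing age column `%s`", age_col))

  breaks <- unique(stats::quantile(age, probs = seq(0, 1, length.out = n_bins + 1)))
  bin <- cut(age, breaks = breaks, include.lowest = TRUE, labels = FALSE)

  n_train <- round(train_fraction * n)
  bin_sizes <- tabulate(bin, nbins = max(bin))
  quota_raw <- train_fraction * bin_sizes
  quota <- floor(quota_raw)
  short <- n_train - sum(quota)
  if (short > 0) {
    order_frac <- order(quota_raw - quota, decreasing = TRUE)
    quota[order_frac[seq_len(short)]] <- quota[order_frac[seq_len(short)]] + 1L
  } else if (short < 0) {
    order_frac <- order(quota_raw - quota)
    take <- order_frac[quota[order_frac] > 0][seq_len(-short)]
    quota[take] <- quota[take] - 1L
  }

  assign <- rep("test", n)
  withr::with_seed(seed, {
    for (b in seq_along(bin_sizes)) {
      rows <- which(bin == b)
      if (length(rows) == 0 || quota[b] == 0) next
      assign[sample(rows, min(quota[b], length(rows)))] <- "train"
    }
  })
  data$split <- factor(assign, levels = c("train", "test"))
  data
}

feature_cols_of <- function(data) {
  fc <- intersect(feature_names(), names(data))
  if (length(fc) == 0) {
    fc <- setdiff(names(data),
                  c("participant_id", "age_years", "age_chron", "split"))
    fc <- fc[vapply(data[fc], is.numeric, TRUE)]
  }
  fc
}

#' Fit the random-forest age regressor
#'
#' Trains a random forest to predict chronological age from the 336
#' accelerometer features. Features are centered and scaled with
#' training-set statistics, which are frozen into the model and re-applied
#' unchanged at prediction time (so no information leaks from later data).
#' Constant features get scale 1 with a warning instead of dividing by zero.
#' Deterministic given `seed`.
#'
#' @param data Tibble holding the feature columns plus `age_col`. Any other
#'   columns (id, split) are ignored.
#' @param seed Integer seed.
#' @param n_trees Number of trees (default 500).
#' @param mtry Features tried per split; default `floor(p / 3)` (regression
#'   convention).
#' @param nodesize Minimum node size below which a node is not split
#'   (default 5).
#' @param age_col Name of the target column (default `"age_years"`).
#' @return An object of class `"actage_rf"`: the tree ensemble plus the
#'   frozen standardization parameters, feature order, out-of-bag MSE and the
#'   hyperparameters used.
#' @export
fit_age_model <- function(data, seed = 1, n_trees = 500, mtry = NULL,
                          nodesize = 5, age_col = "age_years") {
  y <- data[[age_col]]
  if (is.null(y)) abort_schema(sprintf("missing age column `%s`", age_col))
  fc <- feature_cols_of(data)
  X <- as.matrix(data[, fc, drop = FALSE])
  if (anyNA(X) || anyNA(y)) abort_validation("missing values in features or ages")

  center <- colMeans(X)
  scale <- apply(X, 2, stats::sd)
  flat <- !is.finite(scale) | scale == 0
  if (any(flat)) {
    rlang::warn(sprintf("%d constant feature(s); scale set to 1", sum(flat)))
    scale[flat] <- 1
  }
  Xs <- sweep(sweep(X, 2, center), 2, scale, "/")

  p <- ncol(Xs)
  if (is.null(mtry)) mtry <- max(1L, floor(p / 3))
  mtry <- min(as.integer(mtry), p)

  fit <- withr::with_seed(seed, {
    cpp_grow_forest(Xs, as.numeric(y), as.integer(n_trees), mtry,
                    as.integer(nodesize))
  })

  structure(list(
    trees = fit$trees,
    oob_mse = fit$oob_mse,
    center = center,
    scale = scale,
    features = fc,
    n_trees = as.integer(n_trees),
    mtry = mtry,
    nodesize = as.integer(nodesize),
    seed = seed,
    n_train = nrow(Xs),
    age_range = range(y)
  ), class = "actage_rf")
}

#' @export
print.actage_rf <- function(x, ...) {
  cat(sprintf("<actage_rf> %d trees, mtry %d, %d features, n = %d, OOB RMSE %.2f y\n",
              x$n_trees, x$mtry, length(x$features), x$n_train, sqrt(x$oob_mse)))
  invisible(x)
}

standardize_newdata <- function(object, data) {
  missing <- setdiff(object$features, names(data))
  if (length(missing) > 0) {
    abort_schema(sprintf("newdata lacks %d training feature(s), e.g. %s",
                         length(missing), missing[[1]]))
  }
  X <- as.matrix(data[, object$features, drop = FALSE])
  sweep(sweep(X, 2, object$center), 2, object$scale, "/")
}

#' Predict age from a fitted model
#'
#' @param object An `"actage_rf"` model.
#' @param newdata Tibble holding all training features (matched by name; row
#'   order does not affect individual predictions).
#' @param ... Unused.
#' @return Numeric vector of raw predicted ages in years.
#' @export
predict.actage_rf <- function(object, newdata, ...) {
  Xs <- standardize_newdata(object, newdata)
  as.numeric(cpp_predict_forest(object$trees, Xs))
}

#' Raw predicted ages as a tibble
#'
#' Convenience wrapper around [predict.actage_rf()] returning the AgeRecord
#' skeleton: `participant_id`, `age_chron` and `age_pred_raw`.
#'
#' @param model An `"actage_rf"` model.
#' @param data Tibble with `participant_id`, the feature columns, and
#'   `age_col`.
#' @param age_col Name of the chronological-age column.
#' @return Tibble with `participant_id`, `age_chron`, `age_pred_raw`.
#' @export
predict_ages <- function(model, data, age_col = "age_years") {
  tibble::tibble(
    participant_id = data$participant_id,
    age_chron = as.numeric(data[[age_col]]),
    age_pred_raw = predict(model, data)
  )
}

#' Permutation feature importance (%IncMSE)
#'
#' For each feature, the percent increase of the model's mean squared error
#' when that feature's column is randomly permuted in the supplied (ideally
#' held-out) data, averaged over `n_repeats` permutations. Deterministic
#' given `seed`.
#'
#' @param model An `"actage_rf"` model.
#' @param data Tibble with the feature columns and `age_col`.
#' @param n_repeats Permutations per feature (default 10; must be >= 1).
#' @param seed Integer seed.
#' @param age_col Name of the target column.
#' @return Tibble with `feature`, `inc_mse_pct`, plus parsed `stat`
#'   (max/var), `day` and `hour` columns for plotting the day-hour grid.
#' @export
rf_importance <- function(model, data, n_repeats = 10, seed = 1,
                          age_col = "age_years") {
  if (n_repeats < 1) {
    rlang::abort("n_repeats must be >= 1", class = "actage_parameter_error")
  }
  y <- as.numeric(data[[age_col]])
  Xs <- standardize_newdata(model, data)
  imp <- withr::with_seed(seed, {
    cpp_permutation_importance(model$trees, Xs, y, as.integer(n_repeats))
  })
  out <- tibble::tibble(feature = model$features, inc_mse_pct = as.numeric(imp))
  parsed <- regmatches(out$feature,
                       regexec("^(max|var)_d([0-9]+)_h([0-9]+)$", out$feature))
  ok <- lengths(parsed) == 4
  out$stat <- ifelse(ok, vapply(parsed, function(m) m[2], ""), NA_character_)
  out$day <- ifelse(ok, as.integer(vapply(parsed, function(m) m[3], "")), NA_integer_)
  out$hour <- ifelse(ok, as.integer(vapply(parsed, function(m) m[4], "")), NA_integer_)
  out
}

#' Peer-median normalization of predicted ages
#'
#' Corrects the regression-to-the-mean compression of raw random-forest age
#' predictions: each participant's raw prediction is divided by the median
#' raw prediction of peers of similar chronological age (the participant
#' included) and multiplied by their own chronological age:
#' `age_pred_norm_i = age_pred_raw_i / median(raw peers) * age_chron_i`.
#'
#' With the default `peer_window = 0`, peers are participants of the *same*
#' (integer) chronological age, which forces the per-age median deltaAge to
#' zero exactly; a wider window trades that identity for smoother peer
#' medians in sparse ages.
#'
#' @param data Tibble with `age_chron` and `age_pred_raw` (as produced by
#'   [predict_ages()]).
#' @param peer_window Half-width, in years, of the peer age window.
#' @return `data` with an added `age_pred_norm` column.
#' @export
normalize_predictions <- function(data, peer_window = 0) {
  chron <- data$age_chron
  raw <- data$age_pred_raw
  if (is.null(chron) || is.null(raw)) {
    abort_schema("data must have age_chron and age_pred_raw columns")
  }
  uniq <- unique(chron)
  med <- vapply(uniq, function(a) {
    stats::median(raw[abs(chron - a) <= peer_window])
  }, 0.0)
  if (any(!is.finite(med)) || any(med <= 0)) {
    abort_validation("degenerate input: nonpositive peer median of raw predictions")
  }
  data$age_pred_norm <- raw / med[match(chron, uniq)] * chron
  data
}

#' Add the deltaAge column
#'
#' deltaAge is the normalized predicted biological age minus chronological
#' age; positive values indicate accelerated aging, negative decelerated.
#'
#' @param data Tibble with `age_pred_norm` and `age_chron`.
#' @return `data` with an added `delta_age` column.
#' @export
add_delta_age <- function(data) {
  if (is.null(data$age_pred_norm) || is.null(data$age_chron)) {
    abort_schema("data must have age_pred_norm and age_chron columns")
  }
  data$delta_age <- data$age_pred_norm - data$age_chron
  data
}

#' Pearson correlation and RMSE of age predictions
#'
#' @param data Tibble holding the two columns.
#' @param truth,estimate Column names (strings) of chronological and
#'   predicted age.
#' @return One-row tibble with `pearson_r`, `rmse_years`, `n`.
#' @export
evaluate_predictions <- function(data, truth = "age_chron",
                                 estimate = "age_pred_raw") {
  a <- as.numeric(data[[truth]])
  b <- as.numeric(data[[estimate]])
  if (is.null(a) || is.null(b)) abort_schema("evaluation columns not found")
  ok <- is.finite(a) & is.finite(b)
  a <- a[ok]; b <- b[ok]
  if (length(a) < 3) abort_validation("need at least 3 paired finite values")
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    abort_validation("zero-variance vector: Pearson r undefined")
  }
  tibble::tibble(
    pearson_r = stats::cor(a, b),
    rmse_years = sqrt(mean((a - b)^2)),
    n = length(a)
  )
}
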