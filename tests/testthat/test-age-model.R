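test_that("split_train_test is exact, stratified and deterministic", {
  dat <- tibble::tibble(participant_id = 1:100,
                        age_years = rep(18:67, each = 2))
  sp <- split_train_test(dat, 0.70, seed = 3)
  expect_equal(sum(sp$split == "train"), 70)
  expect_equal(sum(sp$split == "test"), 30)
  expect_equal(split_train_test(dat, 0.70, seed = 3)$split, sp$split)
  expect_false(identical(split_train_test(dat, 0.70, seed = 4)$split, sp$split))

  expect_error(split_train_test(dat, 1.2, seed = 1),
               class = "actage_parameter_error")
  expect_error(split_train_test(dat[1:5, ], 0.7, seed = 1),
               class = "actage_validation_error")

  # stratification keeps the two subsets' age means close
  big <- withr::with_seed(9, {
    tibble::tibble(participant_id = 1:1000,
                   age_years = sample(18:85, 1000, replace = TRUE))
  })
  spb <- split_train_test(big, 0.70, seed = 2)
  m_tr <- mean(big$age_years[spb$split == "train"])
  m_te <- mean(big$age_years[spb$split == "test"])
  expect_lt(abs(m_tr - m_te), 2)
})

test_that("forest reproduces constant targets and is seed-deterministic", {
  dat <- withr::with_seed(1, {
    d <- tibble::as_tibble(matrix(rnorm(60 * 8), 60,
                                  dimnames = list(NULL, paste0("f", 1:8))))
    d$age_years <- 50L
    d
  })
  m <- fit_age_model(dat, seed = 2, n_trees = 30)
  expect_true(all(abs(predict(m, dat) - 50) < 1e-10))

  dat$age_years <- withr::with_seed(2, sample(18:85, 60, replace = TRUE))
  m1 <- fit_age_model(dat, seed = 7, n_trees = 40)
  m2 <- fit_age_model(dat, seed = 7, n_trees = 40)
  expect_equal(m1$oob_mse, m2$oob_mse)
  expect_equal(predict(m1, dat), predict(m2, dat))

  # constant feature: scale forced to 1 with a warning, no NaNs downstream
  dat$f1 <- 3
  expect_warning(m3 <- fit_age_model(dat, seed = 1, n_trees = 20), "constant")
  expect_true(all(is.finite(predict(m3, dat))))
})

test_that("predictions are row-order independent and schema-checked", {
  dat <- withr::with_seed(5, {
    d <- tibble::as_tibble(matrix(rnorm(80 * 6), 80,
                                  dimnames = list(NULL, paste0("f", 1:6))))
    d$age_years <- sample(18:85, 80, replace = TRUE)
    d
  })
  m <- fit_age_model(dat, seed = 1, n_trees = 30)
  pred <- predict(m, dat)
  idx <- withr::with_seed(1, sample.int(80))
  expect_equal(predict(m, dat[idx, ]), pred[idx])
  expect_error(predict(m, dat[, -2]), class = "actage_schema_error")
})

test_that("pure-noise features give a null-level held-out correlation", {
  sim <- withr::with_seed(21, {
    n <- 400
    d <- tibble::as_tibble(matrix(rnorm(n * 30), n,
                                  dimnames = list(NULL, paste0("f", 1:30))))
    d$age_years <- sample(18:85, n, replace = TRUE)
    d
  })
  sp <- split_train_test(sim, 0.7, seed = 22)
  m <- fit_age_model(sp[sp$split == "train", ], seed = 22, n_trees = 150)
  test <- sp[sp$split == "test", ]
  r <- cor(test$age_years, predict(m, test))
  expect_lt(abs(r), 1.96 / sqrt(nrow(test)))
})

test_that("permutation importance finds planted signal and dilutes duplicates", {
  sim <- withr::with_seed(31, {
    n <- 260
    age <- sample(18:85, n, replace = TRUE)
    d <- tibble::as_tibble(matrix(rnorm(n * 20), n,
                                  dimnames = list(NULL, paste0("noise", 1:20))))
    d$signal <- age + rnorm(n, 0, 4)
    d$age_years <- age
    d
  })
  sp <- split_train_test(sim, 0.7, seed = 32)
  train <- sp[sp$split == "train", ]
  test <- sp[sp$split == "test", ]

  m <- fit_age_model(train, seed = 32, n_trees = 120, mtry = 7)
  imp <- rf_importance(m, test, n_repeats = 5, seed = 33)
  expect_equal(imp$feature[which.max(imp$inc_mse_pct)], "signal")
  # pure-noise features hover near zero relative to the signal
  noise_imp <- imp$inc_mse_pct[imp$feature != "signal"]
  expect_lt(max(abs(noise_imp)), max(imp$inc_mse_pct) / 3)
  expect_error(rf_importance(m, test, n_repeats = 0),
               class = "actage_parameter_error")

  # duplicating the informative column dilutes each copy's importance
  sim2 <- sim
  sim2$signal2 <- sim2$signal
  train2 <- sim2[sp$split == "train", ]
  test2 <- sim2[sp$split == "test", ]
  m2 <- fit_age_model(train2, seed = 32, n_trees = 120, mtry = 7)
  imp2 <- rf_importance(m2, test2, n_repeats = 5, seed = 33)
  solo <- imp$inc_mse_pct[imp$feature == "signal"]
  dup <- imp2$inc_mse_pct[imp2$feature %in% c("signal", "signal2")]
  expect_true(all(dup < solo))
})

test_that("peer-median normalization matches its defining formula", {
  # raw prediction equal to the peer median maps back to chronological age
  tbl <- tibble::tibble(age_chron = c(60, 60, 60),
                        age_pred_raw = c(50, 55, 60))
  out <- normalize_predictions(tbl, peer_window = 0)
  expect_equal(out$age_pred_norm[2], 60)   # raw 55 is the median of peers

  # raw prediction at 2x the peer median, chronological age 40 -> 80
  tbl2 <- tibble::tibble(age_chron = rep(40, 3),
                         age_pred_raw = c(30, 30, 60))
  out2 <- normalize_predictions(tbl2, peer_window = 0)
  expect_equal(out2$age_pred_norm[3], 80)

  # scale-correcting invariant: raw = c * chron implies norm = chron exactly
  # (exact with same-age peers; a wider window blurs it at the range edges)
  tbl3 <- tibble::tibble(age_chron = rep(18:85, 3),
                         age_pred_raw = 1.37 * rep(18:85, 3))
  out3 <- add_delta_age(normalize_predictions(tbl3, peer_window = 0))
  expect_equal(out3$age_pred_norm, out3$age_chron)
  expect_true(all(abs(out3$delta_age) < 1e-12))

  expect_error(normalize_predictions(
    tibble::tibble(age_chron = c(50, 50), age_pred_raw = c(-1, -2))),
    class = "actage_validation_error")
})

test_that("per-age median deltaAge is pinned to zero by the normalization", {
  recs <- withr::with_seed(41, {
    tibble::tibble(
      age_chron = sample(18:85, 900, replace = TRUE),
      age_pred_raw = NA_real_)
  })
  # a biased, noisy predictor: compresses the age range and adds noise
  recs$age_pred_raw <- withr::with_seed(42, {
    40 + 0.5 * recs$age_chron + rnorm(900, 0, 8)
  })
  out <- add_delta_age(normalize_predictions(recs, peer_window = 0))
  for (a in unique(out$age_chron)) {
    d <- sort(out$delta_age[out$age_chron == a])
    k <- length(d)
    if (k %% 2 == 1) {
      expect_equal(median(d), 0, tolerance = 1e-10)
    } else {
      expect_gte(0, d[k / 2] - 1e-10)
      expect_lte(0, d[k / 2 + 1] + 1e-10)
    }
  }
})

test_that("deltaAge and evaluation metrics follow their definitions", {
  tbl <- tibble::tibble(age_chron = c(60, 60, 60),
                        age_pred_norm = c(70, 50, 60))
  out <- add_delta_age(tbl)
  expect_equal(out$delta_age, c(10, -10, 0))

  perfect <- tibble::tibble(age_chron = c(20, 40, 60), age_pred_raw = c(20, 40, 60))
  ev <- evaluate_predictions(perfect)
  expect_equal(ev$pearson_r, 1)
  expect_equal(ev$rmse_years, 0)

  shifted <- tibble::tibble(age_chron = c(20, 40, 60), age_pred_raw = c(25, 45, 65))
  ev2 <- evaluate_predictions(shifted)
  expect_equal(ev2$pearson_r, 1)
  expect_equal(ev2$rmse_years, 5)

  hand <- tibble::tibble(age_chron = c(1, 2, 3), age_pred_raw = c(2, 4, 6))
  ev3 <- evaluate_predictions(hand)
  expect_equal(ev3$pearson_r, 1)
  expect_equal(ev3$rmse_years, sqrt((1 + 4 + 9) / 3))

  flat <- tibble::tibble(age_chron = c(5, 5, 5), age_pred_raw = c(1, 2, 3))
  expect_error(evaluate_predictions(flat), class = "actage_validation_error")
})

test_that("broom methods summarize the fitted model", {
  dat <- withr::with_seed(51, {
    d <- tibble::as_tibble(matrix(rnorm(60 * 5), 60,
                                  dimnames = list(NULL, paste0("f", 1:5))))
    d$age_years <- sample(18:85, 60, replace = TRUE)
    d
  })
  m <- fit_age_model(dat, seed = 1, n_trees = 25)
  td <- tidy(m)
  expect_equal(nrow(td), 5)
  expect_named(td, c("feature", "center", "scale"))
  gl <- glance(m)
  expect_equal(gl$n_trees, 25)
  expect_true(gl$oob_rmse_years > 0)
})
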