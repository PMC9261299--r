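read_demo_table <- function(path, format = NULL) {
  tbl <- read_table_file(path, format)
  id <- require_col(tbl, c("participant_id", "seqn"), "participant id", path)
  age <- require_col(tbl, c("age_years", "ridageyr"), "age", path)
  out <- tibble::tibble(participant_id = tbl[[id]],
                        age_years = as.integer(tbl[[age]]))
  if (anyDuplicated(out$participant_id)) {
    abort_validation(sprintf("%s: duplicate participant id in demographics", path))
  }
  out
}

read_mortality_table <- function(path, format = NULL) {
  tbl <- read_table_file(path, format)
  id <- require_col(tbl, c("participant_id", "seqn"), "participant id", path)
  v <- require_col(tbl, c("vital_status", "mortstat"), "vital status", path)
  ccol <- find_col(tbl, c("cause_group", "ucod", "ucod_leading"))
  out <- tibble::tibble(participant_id = tbl[[id]],
                        vital_status = vital_from_mortstat(tbl[[v]]),
                        cause_group = if (is.null(ccol)) NA_character_
                                      else as.character(tbl[[ccol]]))
  out$cause_group[!is.na(out$cause_group) & out$cause_group == ""] <- NA_character_
  out$cause_group[out$vital_status != "deceased"] <- NA_character_
  out
}

read_diet_table <- function(path, format = NULL) {
  tbl <- read_table_file(path, format)
  id <- require_col(tbl, c("participant_id", "seqn"), "participant id", path)
  names(tbl)[names(tbl) == id] <- "participant_id"
  names(tbl)[names(tbl) != "participant_id"] <-
    toupper(names(tbl)[names(tbl) != "participant_id"])
  tbl
}

read_rx_table <- function(path, format = NULL) {
  tbl <- read_table_file(path, format)
  id <- require_col(tbl, c("participant_id", "seqn"), "participant id", path)
  d <- require_col(tbl, c("drug", "rxddrug"), "drug name", path)
  tibble::tibble(participant_id = tbl[[id]],
                 drug = normalize_drug_name(tbl[[d]]))
}

#' Pipeline run configuration
#'
#' Gathers all thresholds and input choices of an end-to-end run. Provide
#' either `synth` (a [synth_config()]; the cohort is generated in memory) or
#' `paths`, a named list with elements `activity`, `demographics` and
#' optionally `diet`, `rx`, `mortality` (plus `format`).
#'
#' @param synth Optional [synth_config()].
#' @param paths Optional named list of input paths.
#' @param seed Seed for the train/test split, forest and importance.
#' @param train_fraction Training fraction (default 0.70).
#' @param peer_window Peer half-width for [normalize_predictions()]
#'   (default 0 = same chronological age).
#' @param n_trees,mtry,nodesize Forest hyperparameters (see
#'   [fit_age_model()]).
#' @param min_age_mortality Minimum age for aging-class mortality analysis
#'   (default 60).
#' @param min_age_drugs Minimum age for the drug screen (default 70).
#' @param extreme_cut deltaAge threshold for the extreme-group nutrient test
#'   (default 10 years).
#' @param k_clusters Number of nutrient clusters (default 5).
#' @param out_dir Optional output directory; when given, all stage CSVs plus
#'   a JSON summary are written there.
#' @return A list of class `"run_config"`.
#' @export
run_config <- function(synth = synth_config(), paths = NULL, seed = 1,
                       train_fraction = 0.70, peer_window = 0, n_trees = 500,
                       mtry = NULL, nodesize = 5, min_age_mortality = 60,
                       min_age_drugs = 70, extreme_cut = 10, k_clusters = 5,
                       out_dir = NULL) {
  cfg <- list(synth = synth, paths = paths, seed = seed,
              train_fraction = train_fraction, peer_window = peer_window,
              n_trees = n_trees, mtry = mtry, nodesize = nodesize,
              min_age_mortality = min_age_mortality,
              min_age_drugs = min_age_drugs, extreme_cut = extreme_cut,
              k_clusters = k_clusters, out_dir = out_dir)
  class(cfg) <- "run_config"
  cfg
}

#' Load a run configuration from a YAML file
#'
#' Top-level keys mirror the arguments of [run_config()]; a `synth:` mapping
#' is forwarded to [synth_config()] and a `paths:` mapping selects file
#' inputs instead.
#'
#' @param path YAML file path.
#' @return A `"run_config"`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort_io(sprintf("cannot read config: %s", path))
  y <- yaml::read_yaml(path)
  synth <- NULL
  if (!is.null(y$synth)) synth <- do.call(synth_config, y$synth)
  if (is.null(y$synth) && is.null(y$paths)) synth <- synth_config()
  args <- y[setdiff(names(y), c("synth", "paths"))]
  do.call(run_config, c(list(synth = synth, paths = y$paths), args))
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    rlang::abort(sprintf("pipeline stage `%s` failed: %s", stage,
                         conditionMessage(e)),
                 class = "actage_stage_error", parent = e)
  })
}

#' Run the full biological-age pipeline
#'
#' Executes io -> qc -> features -> age model -> mortality -> screens in
#' order on either a generated synthetic cohort or user-supplied files, and
#' returns every stage table plus a compact summary. Rerunning with an
#' identical config reproduces identical outputs.
#'
#' @param config A [run_config()] (or a path to a YAML file for
#'   [read_run_config()]).
#' @return A list of class `"actage_run"`: `age_records`, `metrics`
#'   (pre/post-normalization r and RMSE on the held-out split), `model`,
#'   `classes`, `proportions`, `decade_tests`, `cause_tests`,
#'   `nutrient_screen`, `nutrient_clusters`, `extreme_tests`, `drug_screen`,
#'   `exclusions`, `counts` (per-stage record counts) and `summary`.
#' @export
run_pipeline <- function(config = run_config()) {
  if (is.character(config)) config <- read_run_config(config)

  counts <- list()
  note_count <- function(stage, n_in, n_out) {
    counts[[length(counts) + 1]] <<- tibble::tibble(stage = stage, n_in = n_in,
                                                    n_out = n_out)
  }

  # -- io ---------------------------------------------------------------------
  tables <- run_stage("io", {
    if (!is.null(config$paths)) {
      p <- config$paths
      if (is.null(p$activity) || is.null(p$demographics)) {
        abort_io("paths must include activity and demographics")
      }
      list(
        activity = read_activity(p$activity, p$format),
        demographics = read_demo_table(p$demographics, p$format),
        mortality = if (!is.null(p$mortality)) read_mortality_table(p$mortality, p$format),
        diet = if (!is.null(p$diet)) read_diet_table(p$diet, p$format),
        rx = if (!is.null(p$rx)) read_rx_table(p$rx, p$format)
      )
    } else {
      unclass(synth_cohort(config$synth))[c("activity", "demographics",
                                            "mortality", "diet", "rx")]
    }
  })
  n_all <- length(unique(tables$activity$participant_id))

  # -- qc + features ----------------------------------------------------------
  retained <- run_stage("qc", qc_filter(tables$activity, tables$demographics))
  exclusions <- qc_exclusions(retained)
  n_keep <- length(unique(retained$participant_id))
  note_count("qc", n_all, n_keep)

  features <- run_stage("features", summarize_weeks(retained))
  features <- dplyr::inner_join(features, tables$demographics, by = "participant_id")
  note_count("features", n_keep, nrow(features))

  # -- age model --------------------------------------------------------------
  model_out <- run_stage("age_model", {
    split_tbl <- split_train_test(features, config$train_fraction, config$seed)
    train <- split_tbl[split_tbl$split == "train", , drop = FALSE]
    model <- fit_age_model(train, seed = config$seed, n_trees = config$n_trees,
                           mtry = config$mtry, nodesize = config$nodesize)
    recs <- predict_ages(model, split_tbl)
    recs$split <- split_tbl$split
    recs <- add_delta_age(normalize_predictions(recs, config$peer_window))
    test <- recs[recs$split == "test", , drop = FALSE]
    metrics <- dplyr::bind_rows(
      dplyr::mutate(evaluate_predictions(test, "age_chron", "age_pred_raw"),
                    stage = "pre_normalization"),
      dplyr::mutate(evaluate_predictions(test, "age_chron", "age_pred_norm"),
                    stage = "post_normalization"))
    list(model = model, age_records = recs, metrics = metrics)
  })
  age_records <- model_out$age_records
  note_count("age_model", nrow(features), nrow(age_records))

  # -- mortality --------------------------------------------------------------
  mort_out <- run_stage("mortality", {
    if (is.null(tables$mortality)) NULL else {
      recs <- dplyr::left_join(age_records, tables$mortality, by = "participant_id")
      recs$vital_status[is.na(recs$vital_status)] <- "unknown"
      classes <- classify_aging(recs, config$min_age_mortality)
      list(classes = classes,
           proportions = test_mortality_proportions(classes),
           decade = test_mortality_by_decade(recs),
           cause = test_mortality_by_cause(recs))
    }
  })
  if (!is.null(mort_out)) {
    note_count("mortality", nrow(age_records), nrow(mort_out$classes))
  }

  # -- screens ----------------------------------------------------------------
  nut_out <- run_stage("nutrient_screen", {
    if (is.null(tables$diet)) NULL else {
      scr <- screen_nutrients(tables$diet, age_records)
      clusters <- tryCatch(cluster_nutrients(scr, config$k_clusters),
                           error = function(e) NULL)
      nutrients <- setdiff(names(tables$diet), "participant_id")
      extremes <- purrr::map_dfr(nutrients, function(nm) {
        test_extreme_groups(tables$diet, age_records, nm, config$extreme_cut)
      })
      list(screen = scr, clusters = clusters, extremes = extremes)
    }
  })
  drug_out <- run_stage("drug_screen", {
    if (is.null(tables$rx)) NULL else {
      screen_drugs(tables$rx, age_records, config$min_age_drugs)
    }
  })

  counts <- dplyr::bind_rows(counts)
  metrics <- model_out$metrics
  summary <- list(
    seed = config$seed,
    n_input = n_all,
    n_retained = n_keep,
    pearson_r_raw = metrics$pearson_r[metrics$stage == "pre_normalization"],
    rmse_raw = metrics$rmse_years[metrics$stage == "pre_normalization"],
    pearson_r_norm = metrics$pearson_r[metrics$stage == "post_normalization"],
    rmse_norm = metrics$rmse_years[metrics$stage == "post_normalization"],
    death_proportions = if (!is.null(mort_out)) {
      as.list(mort_out$proportions[, c("prop_accelerated", "prop_normal",
                                       "prop_decelerated", "p_value")])
    },
    top_decelerating_drug = if (!is.null(drug_out) && nrow(drug_out) > 0) {
      as.list(drug_out[1, c("drug", "n_users", "median_shift", "ks_p")])
    },
    strongest_nutrient_cell = if (!is.null(nut_out)) {
      scr <- nut_out$screen[!is.na(nut_out$screen$r), , drop = FALSE]
      if (nrow(scr) > 0) {
        best <- scr[which.min(scr$r), ]
        list(nutrient = best$nutrient, bin = as.character(best$bin), r = best$r)
      }
    }
  )

  out <- list(
    config = config,
    model = model_out$model,
    age_records = age_records,
    metrics = metrics,
    classes = mort_out$classes,
    proportions = mort_out$proportions,
    decade_tests = mort_out$decade,
    cause_tests = mort_out$cause,
    nutrient_screen = nut_out$screen,
    nutrient_clusters = nut_out$clusters,
    extreme_tests = nut_out$extremes,
    drug_screen = drug_out,
    exclusions = exclusions,
    counts = counts,
    summary = summary
  )
  class(out) <- "actage_run"

  if (!is.null(config$out_dir)) write_run(out, config$out_dir)
  out
}

write_run <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  emit <- function(tbl, stem) {
    if (!is.null(tbl)) {
      readr::write_csv(tbl, file.path(dir, paste0(stem, ".csv")), progress = FALSE)
    }
  }
  emit(run$age_records, "age_records")
  emit(run$metrics, "metrics")
  emit(run$classes, "aging_classes")
  emit(run$proportions, "mortality_proportions")
  emit(run$decade_tests, "decade_tests")
  emit(run$cause_tests, "cause_tests")
  emit(run$nutrient_screen, "nutrient_screen")
  emit(run$nutrient_clusters, "nutrient_clusters")
  emit(run$extreme_tests, "extreme_tests")
  emit(run$drug_screen, "drug_screen")
  emit(run$exclusions, "exclusions")
  emit(run$counts, "stage_counts")
  jsonlite::write_json(run$summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null")
  invisible(dir)
}

#' @export
print.actage_run <- function(x, ...) {
  s <- x$summary
  cat("<actage_run>\n")
  cat(sprintf("  participants: %d input, %d retained after QC\n",
              s$n_input, s$n_retained))
  cat(sprintf("  held-out r: %.3f raw -> %.3f normalized (RMSE %.2f -> %.2f y)\n",
              s$pearson_r_raw, s$pearson_r_norm, s$rmse_raw, s$rmse_norm))
  if (!is.null(s$death_proportions)) {
    cat(sprintf("  death proportions (acc/norm/dec): %.2f / %.2f / %.2f (p = %.3g)\n",
                s$death_proportions$prop_accelerated,
                s$death_proportions$prop_normal,
                s$death_proportions$prop_decelerated,
                s$death_proportions$p_value))
  }
  if (!is.null(s$top_decelerating_drug)) {
    cat(sprintf("  top decelerating drug: %s (n = %d, shift %.1f y, KS p = %.3g)\n",
                s$top_decelerating_drug$drug, s$top_decelerating_drug$n_users,
                s$top_decelerating_drug$median_shift, s$top_decelerating_drug$ks_p))
  }
  invisible(x)
}
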