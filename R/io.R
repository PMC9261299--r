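#' @useDynLib actage, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom rlang .data
#' @importFrom generics tidy glance
"_PACKAGE"

abort_io <- function(msg) rlang::abort(msg, class = "actage_io_error")
abort_schema <- function(msg) rlang::abort(msg, class = "actage_schema_error")
abort_validation <- function(msg) rlang::abort(msg, class = "actage_validation_error")

guess_format <- function(path, format = NULL) {
  if (!is.null(format)) return(match.arg(format, c("csv", "xpt")))
  if (grepl("\\.xpt$", path, ignore.case = TRUE)) "xpt" else "csv"
}

read_table_file <- function(path, format = NULL) {
  if (!file.exists(path)) abort_io(sprintf("cannot read file: %s", path))
  fmt <- guess_format(path, format)
  tbl <- if (fmt == "xpt") {
    haven::read_xpt(path)
  } else {
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  }
  tbl <- tibble::as_tibble(tbl)
  names(tbl) <- tolower(names(tbl))
  tbl
}

# pick the first present alias, or NULL
find_col <- function(tbl, aliases) {
  hit <- intersect(aliases, names(tbl))
  if (length(hit) == 0) NULL else hit[[1]]
}

require_col <- function(tbl, aliases, what, path) {
  col <- find_col(tbl, aliases)
  if (is.null(col)) {
    abort_schema(sprintf(
      "%s: missing required column for %s (accepted names: %s)",
      path, what, paste(aliases, collapse = ", ")))
  }
  col
}

#' Read minute-level activity data
#'
#' Reads an NHANES-style physical activity monitor table (PAXRAW schema) or a
#' canonical CSV into the pipeline's long canonical form: one row per observed
#' minute with columns `participant_id`, `calibrated`, `day` (1-7), `minute`
#' (minute-of-day 0-1439, half-open hours: hour *h* covers minutes
#' `[60h, 60h+60)`), and `intensity` (nonnegative device counts). Sequential
#' minute indices (`PAXN`, 1-10080 across the week) are converted to
#' day/minute-of-day on read. Partial weeks are returned as-is — missing
#' minutes are simply absent rows — and are dealt with by [qc_filter()].
#'
#' Accepted column aliases (case-insensitive): id `participant_id`/`SEQN`;
#' calibration `calibrated`/`PAXCAL` (1 = calibrated) with optional
#' `PAXSTAT` (1 = reliable) folded in conservatively; day `day`/`PAXDAY`;
#' minute `minute`/`PAXMINUT` or sequential `PAXN`; intensity
#' `intensity`/`PAXINTEN`.
#'
#' @param path Path to a `.csv` or `.xpt` file.
#' @param format `"csv"` or `"xpt"`; guessed from the extension when `NULL`.
#' @return A tibble ordered by participant, day and minute.
#' @export
read_activity <- function(path, format = NULL) {
  tbl <- read_table_file(path, format)
  id_col <- require_col(tbl, c("participant_id", "seqn"), "participant id", path)
  int_col <- require_col(tbl, c("intensity", "paxinten"), "intensity", path)
  cal_col <- require_col(tbl, c("calibrated", "paxcal"), "calibration flag", path)
  stat_col <- find_col(tbl, "paxstat")

  day_col <- find_col(tbl, c("day", "paxday"))
  min_col <- find_col(tbl, c("minute", "paxminut"))
  seq_col <- find_col(tbl, "paxn")
  if ((is.null(day_col) || is.null(min_col)) && is.null(seq_col)) {
    abort_schema(sprintf(
      "%s: missing required column for minute index (day+minute, PAXDAY+PAXMINUT, or PAXN)",
      path))
  }

  cal <- tbl[[cal_col]]
  calibrated <- if (is.logical(cal)) cal else cal == 1
  if (!is.null(stat_col)) calibrated <- calibrated & tbl[[stat_col]] == 1

  if (is.null(day_col) || is.null(min_col)) {
    s <- as.integer(tbl[[seq_col]])
    day <- (s - 1L) %/% 1440L + 1L
    minute <- (s - 1L) %% 1440L
  } else {
    day <- as.integer(tbl[[day_col]])
    minute <- as.integer(tbl[[min_col]])
  }

  out <- tibble::tibble(
    participant_id = tbl[[id_col]],
    calibrated = calibrated,
    day = day,
    minute = minute,
    intensity = as.integer(tbl[[int_col]])
  )
  if (any(out$intensity < 0, na.rm = TRUE)) {
    abort_validation(sprintf("%s: negative intensity counts", path))
  }
  if (any(out$day < 1 | out$day > 7, na.rm = TRUE)) {
    abort_validation(sprintf("%s: day outside 1-7", path))
  }
  if (any(out$minute < 0 | out$minute > 1439, na.rm = TRUE)) {
    abort_validation(sprintf("%s: minute outside 0-1439", path))
  }
  dplyr::arrange(out, .data$participant_id, .data$day, .data$minute)
}

vital_from_mortstat <- function(x) {
  if (is.character(x)) {
    out <- tolower(x)
    out[!out %in% c("alive", "deceased")] <- "unknown"
    return(out)
  }
  dplyr::case_when(x == 1 ~ "deceased", x == 0 ~ "alive", TRUE ~ "unknown")
}

#' Read and merge participant-level tables
#'
#' Assembles one record per participant from the demographics table
#' (mandatory) plus optional dietary totals, prescription medications and
#' linked mortality tables. Prescription rows are normalized (uppercased,
#' trimmed, salt suffixes such as "MESYLATE" stripped) and merged into a
#' per-participant drug set. Diet, prescription or mortality rows whose id has
#' no demographics match are dropped with a message. A `cause_group` is kept
#' only for deceased participants.
#'
#' @param demo_path Path to the demographics table (`SEQN`/`RIDAGEYR` or
#'   `participant_id`/`age_years`); required. Ages are integer years,
#'   top-coded at 85 (= "85+").
#' @param diet_path,rx_path,mortality_path Optional paths (`NULL` to skip).
#'   Diet: id + one numeric column per nutrient code. Rx: id +
#'   `RXDDRUG`/`drug`. Mortality: id + `MORTSTAT`/`vital_status` and optional
#'   `UCOD`/`cause_group`.
#' @param format `"csv"`, `"xpt"`, or `NULL` to guess per file.
#' @return A tibble with one row per participant: `participant_id`,
#'   `age_years`, `vital_status` (`"alive"`, `"deceased"`, `"unknown"`),
#'   `cause_group`, and list-columns `nutrients` (named numeric vector) and
#'   `drugs` (character set).
#' @export
read_participants <- function(demo_path, diet_path = NULL, rx_path = NULL,
                              mortality_path = NULL, format = NULL) {
  demo <- read_table_file(demo_path, format)
  id_col <- require_col(demo, c("participant_id", "seqn"), "participant id", demo_path)
  age_col <- require_col(demo, c("age_years", "ridageyr"), "age", demo_path)
  out <- tibble::tibble(
    participant_id = demo[[id_col]],
    age_years = as.integer(demo[[age_col]])
  )
  if (anyDuplicated(out$participant_id)) {
    abort_validation(sprintf("%s: duplicate participant id in demographics", demo_path))
  }
  if (any(out$age_years < 0, na.rm = TRUE)) {
    abort_validation(sprintf("%s: negative ages", demo_path))
  }
  ids <- out$participant_id

  drop_unmatched <- function(tbl, id, what) {
    bad <- !tbl[[id]] %in% ids
    if (any(bad)) {
      rlang::inform(sprintf("%s: dropped %d row(s) with no demographics match",
                            what, sum(bad)))
      tbl <- tbl[!bad, , drop = FALSE]
    }
    tbl
  }

  out$vital_status <- "unknown"
  out$cause_group <- NA_character_
  if (!is.null(mortality_path)) {
    mt <- read_table_file(mortality_path, format)
    mid <- require_col(mt, c("participant_id", "seqn"), "participant id", mortality_path)
    vcol <- require_col(mt, c("vital_status", "mortstat"), "vital status", mortality_path)
    ccol <- find_col(mt, c("cause_group", "ucod", "ucod_leading"))
    mt <- drop_unmatched(mt, mid, "mortality")
    m <- match(mt[[mid]], ids)
    out$vital_status[m] <- vital_from_mortstat(mt[[vcol]])
    if (!is.null(ccol)) out$cause_group[m] <- as.character(mt[[ccol]])
    out$cause_group[out$vital_status != "deceased"] <- NA_character_
  }

  out$nutrients <- rep(list(stats::setNames(numeric(0), character(0))), nrow(out))
  if (!is.null(diet_path)) {
    dt <- read_table_file(diet_path, format)
    did <- require_col(dt, c("participant_id", "seqn"), "participant id", diet_path)
    dt <- drop_unmatched(dt, did, "diet")
    nutr_cols <- setdiff(names(dt), did)
    m <- match(dt[[did]], ids)
    vals <- as.matrix(dt[, nutr_cols, drop = FALSE])
    rn <- toupper(nutr_cols)
    out$nutrients[m] <- lapply(seq_len(nrow(dt)), function(i) {
      stats::setNames(as.numeric(vals[i, ]), rn)
    })
  }

  out$drugs <- rep(list(character(0)), nrow(out))
  if (!is.null(rx_path)) {
    rx <- read_table_file(rx_path, format)
    rid <- require_col(rx, c("participant_id", "seqn"), "participant id", rx_path)
    dcol <- require_col(rx, c("drug", "rxddrug"), "drug name", rx_path)
    rx <- drop_unmatched(rx, rid, "rx")
    rx_norm <- tibble::tibble(id = rx[[rid]],
                              drug = normalize_drug_name(rx[[dcol]]))
    rx_norm <- rx_norm[!is.na(rx_norm$drug) & rx_norm$drug != "", , drop = FALSE]
    sets <- split(rx_norm$drug, rx_norm$id)
    m <- match(names(sets), as.character(ids))
    out$drugs[m] <- lapply(sets, function(d) sort(unique(d)))
  }

  out
}

#' Normalize prescription drug names
#'
#' Uppercases, collapses whitespace and strips trailing salt-form suffixes
#' (e.g. `"DOXAZOSIN MESYLATE"` and `"DOXAZOSIN"` merge), so that the same
#' active compound recorded in different salt forms lands on one name.
#'
#' @param x Character vector of drug names.
#' @return Character vector of normalized names.
#' @export
normalize_drug_name <- function(x) {
  salts <- c("MESYLATE", "BESYLATE", "TOSYLATE", "HYDROCHLORIDE", "HCL",
             "SODIUM", "SULFATE", "SULPHATE", "TARTRATE", "BITARTRATE",
             "MALEATE", "CITRATE", "SUCCINATE", "FUMARATE", "ACETATE",
             "PHOSPHATE", "DIHYDRATE", "MONOHYDRATE", "HYDROBROMIDE")
  out <- toupper(trimws(x))
  out <- gsub("\\s+", " ", out)
  repeat {
    last <- sub("^.*\\s", "", out)
    strip <- grepl(" ", out) & last %in% salts
    if (!any(strip)) break
    out[strip] <- trimws(sub("\\s+\\S+$", "", out[strip]))
  }
  out
}

#' Write the five canonical cohort tables
#'
#' Writes `activity`, `demographics`, `mortality`, `diet` and `rx` tables to a
#' directory, either as canonical CSVs (lowercase canonical headers) or as
#' SAS-transport XPT files using the NHANES column names (`SEQN`, `PAXCAL`,
#' `PAXDAY`, `PAXMINUT`, `PAXINTEN`, `RIDAGEYR`, `MORTSTAT`, `UCOD`,
#' `RXDDRUG`, nutrient codes). Reading the written files back with
#' [read_activity()] / [read_participants()] is lossless in either format.
#'
#' @param cohort A `"synth_cohort"` or any named list with the five tables.
#' @param dir Output directory (created if missing).
#' @param format `"csv"` (default) or `"xpt"`.
#' @return Invisibly, a named character vector of the written paths.
#' @export
write_cohort <- function(cohort, dir, format = c("csv", "xpt")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tables <- cohort[c("activity", "demographics", "mortality", "diet", "rx")]
  if (any(vapply(tables, is.null, TRUE))) {
    abort_validation("cohort must contain activity, demographics, mortality, diet, rx")
  }

  paths <- character(0)
  put <- function(tbl, stem) {
    path <- file.path(dir, paste0(stem, ".", format))
    if (format == "csv") {
      readr::write_csv(tbl, path, progress = FALSE)
    } else {
      haven::write_xpt(tbl, path)
    }
    paths[[stem]] <<- path
  }

  if (format == "csv") {
    put(tables$activity, "activity")
    put(tables$demographics, "demographics")
    put(tables$mortality, "mortality")
    put(tables$diet, "diet")
    put(tables$rx, "rx")
  } else {
    act <- tables$activity
    put(tibble::tibble(SEQN = act$participant_id,
                       PAXCAL = ifelse(act$calibrated, 1, 2),
                       PAXDAY = act$day, PAXMINUT = act$minute,
                       PAXINTEN = act$intensity), "activity")
    put(tibble::tibble(SEQN = tables$demographics$participant_id,
                       RIDAGEYR = tables$demographics$age_years), "demographics")
    mt <- tables$mortality
    put(tibble::tibble(SEQN = mt$participant_id,
                       MORTSTAT = dplyr::case_when(
                         mt$vital_status == "deceased" ~ 1,
                         mt$vital_status == "alive" ~ 0,
                         TRUE ~ NA_real_),
                       UCOD = ifelse(is.na(mt$cause_group), "", mt$cause_group)),
        "mortality")
    diet <- tables$diet
    names(diet)[names(diet) == "participant_id"] <- "SEQN"
    put(diet, "diet")
    put(tibble::tibble(SEQN = tables$rx$participant_id,
                       RXDDRUG = tables$rx$drug), "rx")
  }
  invisible(paths)
}
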