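#' Configuration for the synthetic NHANES-like cohort
#'
#' Builds the full set of knobs for [synth_cohort()]. The defaults describe a
#' cohort in which a single latent "frailty" variable (a per-person offset, in
#' years, of the effective movement age) ties together movement patterns,
#' mortality risk, nutrient intakes and one planted geroprotective drug, so
#' that every downstream association in the pipeline is a testable consequence
#' of one knob.
#'
#' @param n_participants Number of participants.
#' @param seed Integer seed. One RNG stream is derived per output table so
#'   that adding a table never perturbs the others.
#' @param age_range Integer ages are drawn uniformly on this range; 85 is
#'   treated as the NHANES top-code "85+".
#' @param frailty_sd SD (years) of the latent per-person aging-rate offset.
#' @param lifestyle_sd SD (years) of a second latent offset capturing
#'   age-independent differences in how much people move; it blurs the
#'   age signal without feeding mortality.
#' @param activity List of activity-model parameters: `base_mean` (negative
#'   binomial mean count for an active midday minute at age 18), `nb_size`
#'   (dispersion), `decline_floor` (fraction of the age-18 intensity left at
#'   effective age 95), `afternoon_boost` (relative intensity of hours 13-18,
#'   which also decay fastest with age), `p_active_night` (per-minute activity
#'   probability during sleep hours).
#' @param mortality List with `intercept` and `slope`: the probability a
#'   participant is found deceased at follow-up is
#'   `plogis(intercept + slope * (age + frailty))`.
#' @param nutrients Tibble describing the dietary table: columns `code`,
#'   `planted` (logical), `base_log`, `sigma`, and `profile` (list column of 7
#'   per-decade-bin weights tying log intake to negative frailty). Defaults to
#'   [default_nutrient_table()].
#' @param drugs Tibble describing the prescription table: columns `name`,
#'   `rate70` (probability of use among participants aged 70+; younger
#'   participants use at 30% of that rate), and `shift` (years subtracted from
#'   users' frailty; 0 for null drugs). Defaults to [default_drug_table()],
#'   which plants exactly one geroprotector.
#'
#' @return A list with class `"synth_config"`.
#' @export
synth_config <- function(n_participants = 1500,
                         seed = 1,
                         age_range = c(18L, 85L),
                         frailty_sd = 5,
                         lifestyle_sd = 2,
                         activity = list(base_mean = 1200, nb_size = 0.7,
                                         decline_floor = 0.2,
                                         afternoon_boost = 1.6,
                                         p_active_night = 0.02),
                         mortality = list(intercept = -8.5, slope = 0.105),
                         nutrients = default_nutrient_table(),
                         drugs = default_drug_table()) {
  cfg <- list(n_participants = n_participants, seed = seed,
              age_range = as.integer(age_range), frailty_sd = frailty_sd,
              lifestyle_sd = lifestyle_sd, activity = activity,
              mortality = mortality, nutrients = nutrients, drugs = drugs)
  class(cfg) <- "synth_config"
  validate_synth_config(cfg)
  cfg
}

validate_synth_config <- function(cfg) {
  fail <- function(field, msg) {
    rlang::abort(sprintf("invalid synth_config field `%s`: %s", field, msg),
                 class = "actage_config_error")
  }
  if (!is.numeric(cfg$n_participants) || length(cfg$n_participants) != 1 ||
      cfg$n_participants < 1) {
    fail("n_participants", "must be a single positive number")
  }
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1) fail("seed", "must be a single number")
  if (length(cfg$age_range) != 2 || cfg$age_range[1] < 0 ||
      cfg$age_range[2] < cfg$age_range[1]) {
    fail("age_range", "must be an increasing pair of nonnegative ages")
  }
  if (!is.numeric(cfg$frailty_sd) || cfg$frailty_sd < 0) fail("frailty_sd", "must be >= 0")
  if (!is.numeric(cfg$lifestyle_sd) || cfg$lifestyle_sd < 0) fail("lifestyle_sd", "must be >= 0")
  act <- cfg$activity
  for (nm in c("base_mean", "nb_size", "decline_floor", "afternoon_boost", "p_active_night")) {
    if (is.null(act[[nm]]) || !is.numeric(act[[nm]]) || act[[nm]] < 0) {
      fail(paste0("activity$", nm), "must be a nonnegative number")
    }
  }
  if (act$decline_floor > 1) fail("activity$decline_floor", "must be in [0, 1]")
  for (nm in c("intercept", "slope")) {
    if (is.null(cfg$mortality[[nm]]) || !is.numeric(cfg$mortality[[nm]])) {
      fail(paste0("mortality$", nm), "must be numeric")
    }
  }
  nut <- cfg$nutrients
  if (!all(c("code", "planted", "base_log", "sigma", "profile") %in% names(nut))) {
    fail("nutrients", "must have columns code, planted, base_log, sigma, profile")
  }
  if (any(vapply(nut$profile, length, 1L) != 7L)) {
    fail("nutrients$profile", "each profile must have 7 per-decade weights")
  }
  if (any(vapply(nut$profile, function(w) any(abs(w) > 1), TRUE))) {
    fail("nutrients$profile", "weights must lie in [-1, 1]")
  }
  drg <- cfg$drugs
  if (!all(c("name", "rate70", "shift") %in% names(drg))) {
    fail("drugs", "must have columns name, rate70, shift")
  }
  if (any(drg$rate70 < 0 | drg$rate70 > 1)) fail("drugs$rate70", "rates must be in [0, 1]")
  invisible(cfg)
}

#' Default nutrient table for the synthetic cohort
#'
#' Fourteen NHANES-style dietary-total codes. Two are planted: fiber
#' (`DR1TFIBE`) with a late-peaking association profile whose strongest link
#' to decelerated aging falls in the 50-59 decade bin, and magnesium
#' (`DR1TMAGN`) with the same shape at lower amplitude. The remainder are null
#' (log-normal intakes independent of frailty).
#'
#' @return A tibble with columns `code`, `planted`, `base_log`, `sigma`,
#'   `profile`.
#' @export
default_nutrient_table <- function() {
  late_peak <- c(0.02, 0.05, 0.12, 0.45, 0.15, 0.08, 0.05)
  null_profile <- rep(0, 7)
  tibble::tibble(
    code = c("DR1TFIBE", "DR1TMAGN", "DR1TKCAL", "DR1TPROT", "DR1TCARB",
             "DR1TTFAT", "DR1TSUGR", "DR1TCALC", "DR1TIRON", "DR1TZINC",
             "DR1TVITC", "DR1TATOC", "DR1TSODI", "DR1TPOTA"),
    planted = c(TRUE, TRUE, rep(FALSE, 12)),
    base_log = log(c(15, 280, 2000, 80, 250, 75, 110, 900, 14, 11, 80, 7, 3400, 2600)),
    sigma = c(0.45, 0.35, 0.30, 0.32, 0.30, 0.35, 0.50, 0.40, 0.35, 0.35,
              0.60, 0.45, 0.30, 0.30),
    profile = c(list(late_peak), list(0.78 * late_peak),
                rep(list(null_profile), 12))
  )
}

#' Default prescription-drug table for the synthetic cohort
#'
#' Thirty common generic drug names with age-weighted usage rates. Exactly one
#' drug is planted as a geroprotector: `DOXAZOSIN`, used by 2% of participants
#' aged 70+ and shifting its users' frailty by -6 years (i.e. their movement
#' looks six years younger, and their mortality risk drops accordingly). All
#' other drugs are null.
#'
#' @return A tibble with columns `name`, `rate70`, `shift`.
#' @export
default_drug_table <- function() {
  null_names <- c(
    "LISINOPRIL", "ATORVASTATIN", "METFORMIN", "SIMVASTATIN", "AMLODIPINE",
    "OMEPRAZOLE", "METOPROLOL", "LEVOTHYROXINE", "HYDROCHLOROTHIAZIDE",
    "FUROSEMIDE", "ATENOLOL", "WARFARIN", "GLIPIZIDE", "ALBUTEROL",
    "PREDNISONE", "RANITIDINE", "SERTRALINE", "GABAPENTIN", "ALENDRONATE",
    "CLOPIDOGREL", "VERAPAMIL", "DILTIAZEM", "LOSARTAN", "DIGOXIN",
    "TAMSULOSIN", "AMOXICILLIN", "CAPTOPRIL", "POTASSIUM CHLORIDE",
    "ASPIRIN")
  tibble::tibble(
    name = c("DOXAZOSIN", null_names),
    rate70 = c(0.02,
               rep(c(0.22, 0.15, 0.10, 0.06, 0.03), length.out = length(null_names))),
    shift = c(-6, rep(0, length(null_names)))
  )
}

# per-table RNG streams: deterministic sub-seeds below 2^31
stream_seed <- function(seed, offset) {
  (abs(as.integer(seed)) %% 100000000L) * 10L + as.integer(offset)
}

hour_activity_prob <- function(p_night) {
  c(rep(p_night, 6),            # 0-5 sleep
    0.20, 0.45,                 # 6-7 waking
    rep(0.65, 4),               # 8-11 morning
    rep(0.70, 6),               # 12-17 midday/afternoon
    rep(0.60, 3),               # 18-20 evening
    0.40, 0.15, 0.05)           # 21-23 winding down
}

hour_mean_shape <- function(afternoon_boost) {
  s <- c(rep(0.15, 6), 0.5, 0.8, rep(1.0, 5), rep(1, 6), rep(0.8, 3),
         0.5, 0.3, 0.2)
  s[14:19] <- afternoon_boost   # hours 13-18
  s
}

#' Generate a synthetic NHANES-like cohort
#'
#' Produces the five canonical tables consumed by the pipeline — minute-level
#' activity, demographics, linked mortality, dietary totals and prescription
#' medications — with planted, configurable effects. Each participant has a
#' latent frailty `f ~ N(0, frailty_sd)` shifting their effective "movement
#' age" to `age + f`; minute counts follow a zero-inflated negative binomial
#' whose hourly mean (hence max and variance) decays with effective age,
#' afternoon hours fastest; the death indicator follows a logistic model in
#' `age + f`; planted nutrients correlate with `-f` per their decade profile;
#' and users of the planted geroprotective drug have `f` reduced by the stated
#' shift before any downstream table is drawn.
#'
#' Deterministic given `config$seed`; each table draws from its own derived
#' RNG stream.
#'
#' @param config A [synth_config()].
#' @return A list of class `"synth_cohort"` with tibbles `activity`,
#'   `demographics`, `mortality`, `diet`, `rx`, and a `manifest` list holding
#'   the config and the per-participant latent truth (the answer key used by
#'   recovery tests).
#' @export
synth_cohort <- function(config = synth_config()) {
  validate_synth_config(config)
  n <- as.integer(config$n_participants)
  ids <- 100001L + seq_len(n) - 1L

  # -- stream 1: demographics + latent structure ------------------------------
  demo <- withr::with_seed(stream_seed(config$seed, 1L), {
    age <- sample(seq(config$age_range[1], config$age_range[2]), n, replace = TRUE)
    f0 <- stats::rnorm(n, 0, config$frailty_sd)
    u <- stats::rnorm(n, 0, config$lifestyle_sd)
    list(age = as.integer(age), f0 = f0, u = u)
  })

  # -- stream 2: prescriptions (drug users chosen from ages alone) ------------
  drugs <- config$drugs
  use_mat <- withr::with_seed(stream_seed(config$seed, 2L), {
    vapply(seq_len(nrow(drugs)), function(k) {
      p <- ifelse(demo$age >= 70, drugs$rate70[k], 0.3 * drugs$rate70[k])
      stats::rbinom(n, 1L, p) == 1L
    }, logical(n))
  })
  if (n == 1L) use_mat <- matrix(use_mat, nrow = 1L)

  # planted drugs shift their users' frailty before anything downstream
  f <- demo$f0
  for (k in which(drugs$shift != 0)) f[use_mat[, k]] <- f[use_mat[, k]] + drugs$shift[k]

  rx <- tibble::tibble(
    participant_id = rep(ids, times = rowSums(use_mat)),
    drug = unlist(lapply(seq_len(n), function(i) drugs$name[use_mat[i, ]]),
                  use.names = FALSE)
  )

  # -- stream 3: minute-level activity ---------------------------------------
  eff_age <- pmin(pmax(demo$age + f + demo$u, 18), 95)
  act <- config$activity
  scale_p <- 1 - (1 - act$decline_floor) * (eff_age - 18) / (95 - 18)

  n_min <- 7L * 1440L
  minute <- rep.int(0:1439, 7L)
  day <- rep(1:7, each = 1440L)
  hour1 <- minute %/% 60L + 1L
  p_hour <- hour_activity_prob(act$p_active_night)
  mu_shape <- hour_mean_shape(act$afternoon_boost)
  afternoon <- hour1 %in% 14:19

  intensity <- withr::with_seed(stream_seed(config$seed, 3L), {
    s_rep <- rep(scale_p, each = n_min)
    p <- rep(p_hour[hour1], times = n) * (0.55 + 0.45 * s_rep)
    active <- stats::rbinom(n * n_min, 1L, p) == 1L
    mu <- act$base_mean * rep(mu_shape[hour1], times = n) * s_rep^1.3
    mu[rep(afternoon, times = n)] <- mu[rep(afternoon, times = n)] *
      s_rep[rep(afternoon, times = n)]^0.7
    out <- integer(n * n_min)
    out[active] <- stats::rnbinom(sum(active), size = act$nb_size, mu = mu[active])
    out
  })

  activity <- tibble::tibble(
    participant_id = rep(ids, each = n_min),
    calibrated = TRUE,
    day = rep.int(day, n),
    minute = rep.int(minute, n),
    intensity = intensity
  )

  # -- stream 4: linked mortality --------------------------------------------
  mort <- withr::with_seed(stream_seed(config$seed, 4L), {
    p_death <- stats::plogis(config$mortality$intercept +
                               config$mortality$slope * (demo$age + f))
    dead <- stats::rbinom(n, 1L, p_death) == 1L
    causes <- c("Diseases of heart", "Malignant neoplasms",
                "Chronic lower respiratory diseases (J40-J47)",
                "Alzheimer's disease", "Diabetes mellitus",
                "Nephritis, nephrotic syndrome and nephrosis",
                "Accidents", "All other causes")
    base_w <- c(0.30, 0.28, 0.08, 0.06, 0.05, 0.05, 0.08, 0.10)
    cause <- rep(NA_character_, n)
    for (i in which(dead)) {
      w <- base_w
      w[3] <- w[3] * exp(0.2 * f[i])   # respiratory deaths skew to high frailty
      cause[i] <- sample(causes, 1L, prob = w / sum(w))
    }
    list(dead = dead, cause = cause)
  })

  mortality <- tibble::tibble(
    participant_id = ids,
    vital_status = ifelse(mort$dead, "deceased", "alive"),
    cause_group = mort$cause
  )

  # -- stream 5: dietary totals ----------------------------------------------
  bin_idx <- decade_bin_index(demo$age)
  z_f <- if (config$frailty_sd > 0) -f / config$frailty_sd else rep(0, n)
  diet_cols <- withr::with_seed(stream_seed(config$seed, 5L), {
    lapply(seq_len(nrow(config$nutrients)), function(k) {
      row <- config$nutrients[k, ]
      w <- row$profile[[1]][bin_idx]
      z <- w * z_f + sqrt(pmax(0, 1 - w^2)) * stats::rnorm(n)
      round(exp(row$base_log + row$sigma * z), 2)
    })
  })
  diet <- tibble::as_tibble(stats::setNames(diet_cols, config$nutrients$code))
  diet <- dplyr::bind_cols(tibble::tibble(participant_id = ids), diet)

  out <- list(
    activity = activity,
    demographics = tibble::tibble(participant_id = ids, age_years = demo$age),
    mortality = mortality,
    diet = diet,
    rx = rx,
    manifest = list(config = config,
                    truth = tibble::tibble(participant_id = ids,
                                           age_years = demo$age,
                                           frailty = f,
                                           frailty_base = demo$f0,
                                           lifestyle = demo$u,
                                           eff_age = eff_age))
  )
  class(out) <- "synth_cohort"
  out
}

#' @export
print.synth_cohort <- function(x, ...) {
  cat("<synth_cohort> ", nrow(x$demographics), " participants, ",
      nrow(x$activity), " activity minutes, seed ",
      x$manifest$config$seed, "\n", sep = "")
  invisible(x)
}

#' Miniature cohort fixture with planted QC violators
#'
#' A 30-participant cohort (or even smaller with `tiny = TRUE` semantics kept
#' for symmetry) whose first three participants each violate exactly one QC
#' rule: participant 1 has a day with 143/1440 (9.93%) nonzero minutes,
#' participant 2 is aged 17, and participant 3 wore an uncalibrated device.
#' Everything else passes QC. Deterministic; regenerating with the same seed
#' yields byte-identical CSVs.
#'
#' @param tiny If `TRUE` (default) `n = 30`; otherwise `n = 120`.
#' @param seed Seed forwarded to [synth_config()].
#' @return A `"synth_cohort"` list (see [synth_cohort()]).
#' @export
synth_fixture <- function(tiny = TRUE, seed = 42) {
  n <- if (tiny) 30L else 120L
  cohort <- synth_cohort(synth_config(n_participants = n, seed = seed))
  ids <- cohort$demographics$participant_id

  # participant 1: day 3 gets exactly 143 nonzero minutes (rule c violator)
  v1 <- ids[1]
  sel <- cohort$activity$participant_id == v1 & cohort$activity$day == 3
  cohort$activity$intensity[sel] <- 0L
  first143 <- which(sel)[1:143]
  cohort$activity$intensity[first143] <- 100L
  # make sure participant 1 passes every other rule
  cohort$demographics$age_years[1] <- max(cohort$demographics$age_years[1], 30L)

  # participant 2: under-age (rule d violator)
  cohort$demographics$age_years[2] <- 17L

  # participant 3: uncalibrated device (rule a violator)
  cohort$activity$calibrated[cohort$activity$participant_id == ids[3]] <- FALSE

  # guarantee the remaining participants are adults
  grown <- cohort$demographics$age_years < 18
  grown[2] <- FALSE
  cohort$demographics$age_years[grown] <- 18L + (ids[grown] %% 60L)

  cohort$manifest$planted_violators <- tibble::tibble(
    participant_id = ids[1:3],
    rule = c("low_activity_day", "under_age", "not_calibrated")
  )
  cohort
}
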