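test_that("read_activity handles canonical and NHANES CSV layouts", {
  dir <- withr::local_tempdir()

  # all-zero week, NHANES column names, day + minute-of-day layout
  wk <- toy_week(id = 101L, fill = 0L)
  nh <- tibble::tibble(SEQN = wk$participant_id, PAXCAL = 1, PAXSTAT = 1,
                       PAXDAY = wk$day, PAXMINUT = wk$minute, PAXINTEN = wk$intensity)
  path <- file.path(dir, "pax.csv")
  readr::write_csv(nh, path)
  got <- read_activity(path)
  expect_equal(nrow(got), 7 * 1440)
  expect_true(all(got$intensity == 0))
  expect_true(all(got$calibrated))
  expect_equal(sort(unique(got$day)), 1:7)

  # sequential minute index converts to day/minute-of-day
  seq_tbl <- tibble::tibble(SEQN = 101L, PAXCAL = 1, PAXN = 1:10080,
                            PAXINTEN = wk$intensity)
  path2 <- file.path(dir, "pax_seq.csv")
  readr::write_csv(seq_tbl, path2)
  got2 <- read_activity(path2)
  expect_equal(got2$day, got$day)
  expect_equal(got2$minute, got$minute)

  # row order does not affect the canonical result
  shuf <- nh[sample.int(nrow(nh)), ]
  path3 <- file.path(dir, "pax_shuf.csv")
  readr::write_csv(shuf, path3)
  expect_equal(read_activity(path3), got)

  # six-day week comes back partial, to be caught by QC
  six <- nh[nh$PAXDAY <= 6, ]
  path4 <- file.path(dir, "pax6.csv")
  readr::write_csv(six, path4)
  got6 <- read_activity(path4)
  expect_equal(nrow(got6), 6 * 1440)
  filtered <- qc_filter(got6, toy_demo(101L, 40L))
  expect_equal(nrow(filtered), 0)
  expect_equal(qc_exclusions(filtered)$rule, "incomplete_week")
})

test_that("read_activity raises typed I/O, schema and validation errors", {
  dir <- withr::local_tempdir()
  expect_error(read_activity(file.path(dir, "nope.csv")), class = "actage_io_error")

  bad <- tibble::tibble(SEQN = 1L, PAXDAY = 1L, PAXMINUT = 0L, PAXINTEN = 5L)
  path <- file.path(dir, "bad.csv")
  readr::write_csv(bad, path)
  expect_error(read_activity(path), "calibration", class = "actage_schema_error")

  neg <- tibble::tibble(SEQN = 1L, PAXCAL = 1, PAXDAY = 1L, PAXMINUT = 0L,
                        PAXINTEN = -3L)
  path2 <- file.path(dir, "neg.csv")
  readr::write_csv(neg, path2)
  expect_error(read_activity(path2), "negative", class = "actage_validation_error")
})

test_that("synthetic cohort round-trips through CSV and XPT identically", {
  co <- tiny_fixture()
  dir_csv <- withr::local_tempdir()
  dir_xpt <- withr::local_tempdir()
  write_cohort(co, dir_csv, "csv")
  write_cohort(co, dir_xpt, "xpt")

  act_csv <- read_activity(file.path(dir_csv, "activity.csv"))
  act_xpt <- read_activity(file.path(dir_xpt, "activity.xpt"))
  orig <- dplyr::arrange(co$activity, participant_id, day, minute)
  expect_equal(as.data.frame(act_csv), as.data.frame(orig))
  expect_equal(as.data.frame(act_xpt), as.data.frame(act_csv))

  pp_csv <- read_participants(file.path(dir_csv, "demographics.csv"),
                              diet_path = file.path(dir_csv, "diet.csv"),
                              rx_path = file.path(dir_csv, "rx.csv"),
                              mortality_path = file.path(dir_csv, "mortality.csv"))
  pp_xpt <- read_participants(file.path(dir_xpt, "demographics.xpt"),
                              diet_path = file.path(dir_xpt, "diet.xpt"),
                              rx_path = file.path(dir_xpt, "rx.xpt"),
                              mortality_path = file.path(dir_xpt, "mortality.xpt"))
  expect_equal(as.data.frame(pp_csv), as.data.frame(pp_xpt))

  expect_equal(pp_csv$age_years, co$demographics$age_years)
  expect_equal(pp_csv$vital_status, co$mortality$vital_status)
  expect_equal(pp_csv$cause_group, co$mortality$cause_group)
  # drug sets reassemble from the long rx table
  expected_drugs <- lapply(co$demographics$participant_id, function(id) {
    sort(unique(co$rx$drug[co$rx$participant_id == id]))
  })
  expect_equal(pp_csv$drugs, expected_drugs)
  # nutrient maps carry every code
  expect_true(all(vapply(pp_csv$nutrients, length, 1L) == ncol(co$diet) - 1L))
  expect_equal(unname(pp_csv$nutrients[[5]]),
               as.numeric(co$diet[5, -1]))
})

test_that("read_participants merges, dedups and validates", {
  dir <- withr::local_tempdir()
  demo <- tibble::tibble(SEQN = c(1L, 2L), RIDAGEYR = c(40L, 85L))
  readr::write_csv(demo, file.path(dir, "demo.csv"))

  # demographics only: unknown vital status, empty sets
  pp <- read_participants(file.path(dir, "demo.csv"))
  expect_equal(pp$vital_status, c("unknown", "unknown"))
  expect_equal(lengths(pp$drugs), c(0L, 0L))
  expect_equal(pp$age_years, c(40L, 85L))

  # two salt forms of the same drug merge to a set of size 1
  rx <- tibble::tibble(SEQN = c(1L, 1L, 2L),
                       RXDDRUG = c("DOXAZOSIN MESYLATE", "Doxazosin ", "ASPIRIN"))
  readr::write_csv(rx, file.path(dir, "rx.csv"))
  pp2 <- read_participants(file.path(dir, "demo.csv"),
                           rx_path = file.path(dir, "rx.csv"))
  expect_equal(pp2$drugs[[1]], "DOXAZOSIN")
  expect_equal(pp2$drugs[[2]], "ASPIRIN")

  # unmatched rows are dropped with a message
  rx2 <- tibble::tibble(SEQN = c(1L, 99L), RXDDRUG = c("ASPIRIN", "GHOST"))
  readr::write_csv(rx2, file.path(dir, "rx2.csv"))
  expect_message(
    pp3 <- read_participants(file.path(dir, "demo.csv"),
                             rx_path = file.path(dir, "rx2.csv")),
    "no demographics match")
  expect_equal(pp3$drugs[[1]], "ASPIRIN")

  # duplicate id in demographics is a validation error
  dup <- tibble::tibble(SEQN = c(1L, 1L), RIDAGEYR = c(40L, 41L))
  readr::write_csv(dup, file.path(dir, "dup.csv"))
  expect_error(read_participants(file.path(dir, "dup.csv")),
               "duplicate", class = "actage_validation_error")
})

test_that("drug-name normalization strips salts and whitespace", {
  expect_equal(normalize_drug_name("  doxazosin   mesylate "), "DOXAZOSIN")
  expect_equal(normalize_drug_name("METOPROLOL TARTRATE"), "METOPROLOL")
  expect_equal(normalize_drug_name("VERAPAMIL HYDROCHLORIDE"), "VERAPAMIL")
  # multi-word salt chains strip fully; bare salt-like names survive
  expect_equal(normalize_drug_name("METFORMIN HCL"), "METFORMIN")
  expect_equal(normalize_drug_name("POTASSIUM CHLORIDE"), "POTASSIUM CHLORIDE")
  expect_equal(normalize_drug_name("SODIUM"), "SODIUM")
})
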