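test_that("BH adjustment matches the step-up oracle and validates input", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 0)), class = "actage_validation_error")
  expect_error(bh_adjust(c(0.5, 1.2)), class = "actage_validation_error")

  withr::with_seed(101, {
    for (i in 1:25) {
      p <- runif(sample(1:20, 1))
      adj <- bh_adjust(p)
      expect_equal(adj, bh_oracle(p), tolerance = 1e-12)
      expect_true(all(adj >= p - 1e-12))
      expect_true(all(adj <= 1))
    }
  })
})

make_age_records <- function(ages, deltas, ids = seq_along(ages)) {
  tibble::tibble(participant_id = ids, age_chron = ages, delta_age = deltas)
}

test_that("nutrient screen recovers exact and null correlations per bin", {
  recs <- withr::with_seed(111, {
    make_age_records(rep(c(25, 55), each = 100), rnorm(200, 0, 5))
  })
  diet <- tibble::tibble(
    participant_id = recs$participant_id,
    NUTNEG = -recs$delta_age,                       # r = -1 in both bins
    NUTNULL = withr::with_seed(112, rnorm(200)))
  scr <- screen_nutrients(diet, recs)
  neg <- scr[scr$nutrient == "NUTNEG" & scr$bin %in% c("18-29", "50-59"), ]
  expect_equal(neg$r, c(-1, -1))
  null_50 <- scr[scr$nutrient == "NUTNULL" & scr$bin == "50-59", ]
  expect_lt(abs(null_50$r), 1.96 / sqrt(null_50$n) * 1.5)
  # bins with no participants stay missing
  expect_true(all(is.na(scr$r[scr$bin == "80+"])))
  # adjusted p never drops below raw p
  ok <- !is.na(scr$p_value)
  expect_true(all(scr$adj_p[ok] >= scr$p_value[ok] - 1e-12))

  # affine rescaling of a nutrient's units leaves r unchanged
  diet2 <- diet
  diet2$NUTNEG <- 3.7 * diet2$NUTNEG + 12
  scr2 <- screen_nutrients(diet2, recs)
  expect_equal(scr2$r, scr$r, tolerance = 1e-12)

  # zero-variance intake in a bin is a missing cell, not an error
  diet3 <- diet
  diet3$NUTNEG[recs$age_chron == 25] <- 4
  scr3 <- screen_nutrients(diet3, recs)
  expect_true(is.na(scr3$r[scr3$nutrient == "NUTNEG" & scr3$bin == "18-29"]))
})

test_that("a late-peaking planted nutrient is most negative in its target bin", {
  sim <- withr::with_seed(121, {
    n <- 1200
    ages <- sample(18:85, n, replace = TRUE)
    f <- rnorm(n, 0, 5)
    profile <- c(0.05, 0.1, 0.2, 0.55, 0.2, 0.1, 0.05)
    w <- profile[decade_of(ages)]
    intake <- exp(log(15) + 0.4 * (w * (-f / 5) + sqrt(1 - w^2) * rnorm(n)))
    list(recs = make_age_records(ages, f + rnorm(n, 0, 1)),
         diet = tibble::tibble(participant_id = seq_len(n), FIBER = intake))
  })
  scr <- screen_nutrients(sim$diet, sim$recs)
  expect_equal(as.character(scr$bin[which.min(scr$r)]), "50-59")
})

test_that("nutrient profile clustering separates planted shapes", {
  mk_screen <- function(profiles) {
    purrr::imap_dfr(profiles, function(pr, nm) {
      tibble::tibble(nutrient = nm, bin = decade_bins()$label, n = 100,
                     r = pr, p_value = 0.5, adj_p = 0.5)
    })
  }
  flat <- rep(0, 7)
  late <- c(0, 0, -0.1, -0.4, -0.2, -0.1, 0)
  profiles <- c(
    stats::setNames(lapply(1:4, function(i) flat + i * 0.005), paste0("flat", 1:4)),
    stats::setNames(lapply(1:4, function(i) late + i * 0.005), paste0("late", 1:4)))
  cl <- cluster_nutrients(mk_screen(profiles), k = 2)
  groups <- split(cl$nutrient, cl$cluster)
  expect_setequal(vapply(groups, function(g) paste(sort(substr(g, 1, 4)),
                                                   collapse = ""), ""),
                  c("flatflatflatflat", "latelatelatelate"))

  # identical rows share a cluster; k = n gives singletons
  two <- mk_screen(list(a = late, b = late, c = flat))
  cl2 <- cluster_nutrients(two, k = 2)
  expect_equal(cl2$cluster[cl2$nutrient == "a"], cl2$cluster[cl2$nutrient == "b"])
  cl3 <- cluster_nutrients(two, k = 3)
  expect_equal(length(unique(cl3$cluster)), 3)
  expect_error(cluster_nutrients(two, k = 5), class = "actage_parameter_error")

  # nutrients with missing cells are dropped with a message
  withmiss <- mk_screen(list(a = late, b = flat, c = flat))
  withmiss$r[withmiss$nutrient == "a" & withmiss$bin == "80+"] <- NA
  expect_message(cl4 <- cluster_nutrients(withmiss, k = 2), "dropped")
  expect_false("a" %in% cl4$nutrient)
})

test_that("extreme-deltaAge group test behaves at both ends", {
  # identical intake distributions: p = 1
  recs <- make_age_records(rep(60, 20), c(rep(-15, 10), rep(15, 10)))
  diet <- tibble::tibble(participant_id = recs$participant_id,
                         NUT = rep(c(1, 2, 3, 4, 5), 4))
  res <- test_extreme_groups(diet, recs, "NUT")
  expect_true(res$testable)
  expect_equal(res$p_value, 1)

  # 3 SD higher intake in the decelerated group
  sim <- withr::with_seed(131, {
    recs <- make_age_records(rep(60, 50), c(rep(-15, 25), rep(15, 25)))
    diet <- tibble::tibble(
      participant_id = recs$participant_id,
      NUT = c(rnorm(25, 13, 1), rnorm(25, 10, 1)))
    list(recs = recs, diet = diet)
  })
  res2 <- test_extreme_groups(sim$diet, sim$recs, "NUT")
  expect_lt(res2$p_value, 1e-4)
  expect_gt(res2$mean_decelerated, res2$mean_accelerated)

  # nobody beyond +/-10 years: untestable
  tame <- make_age_records(rep(60, 20), rnorm(20, 0, 2))
  res3 <- test_extreme_groups(diet, tame, "NUT")
  expect_false(res3$testable)

  expect_error(test_extreme_groups(diet, recs, "MISSING"),
               class = "actage_schema_error")
})

test_that("drug screen KS test, shifts and rank scores follow the contract", {
  # users whose deltas replicate the population distribution: D = 0, p = 1
  recs <- make_age_records(rep(75, 50), rep(c(1, 2, 3, 4, 5), 10))
  rx <- tibble::tibble(participant_id = 1:5, drug = "MIRROR")  # deltas 1..5
  scr <- screen_drugs(rx, recs)
  expect_equal(scr$ks_p, 1)
  expect_equal(scr$median_shift, 0)
  expect_equal(scr$rank_score, 0)

  # 10 users below every other value in a large population: KS D = 1
  big <- withr::with_seed(141, {
    make_age_records(rep(75, 1932), c(rnorm(1922, 0, 5), rnorm(10, -40, 0.5)),
                     ids = 1:1932)
  })
  rx2 <- tibble::tibble(participant_id = 1923:1932, drug = "SINKER")
  scr2 <- screen_drugs(rx2, big)
  expect_lt(scr2$ks_p, 1e-8)
  expect_lt(scr2$median_shift, 0)
  expect_gt(scr2$rank_score, 8)   # log10(p) * sign(shift) > 8

  # age filter: users below min_age are invisible to the screen
  yng <- make_age_records(c(rep(75, 30), rep(50, 5)), rnorm(35), ids = 1:35)
  rx3 <- tibble::tibble(participant_id = 31:35, drug = "YOUNGDRUG")
  expect_equal(nrow(screen_drugs(rx3, yng)), 0)
  expect_error(screen_drugs(rx3, yng[yng$age_chron >= 90, ]),
               class = "actage_validation_error")

  # polypharmacy: duplicated prescription rows count once
  rx4 <- tibble::tibble(participant_id = c(1, 1, 2), drug = "DUP")
  scr4 <- screen_drugs(rx4, recs)
  expect_equal(scr4$n_users, 2L)
})

test_that("a planted geroprotector tops the ranking among null drugs", {
  sim <- withr::with_seed(151, {
    n <- 600
    recs <- make_age_records(rep(c(75, 80), n / 2), rnorm(n, 0, 6))
    rx <- purrr::map_dfr(1:30, function(k) {
      tibble::tibble(participant_id = sample(seq_len(n), 40),
                     drug = sprintf("NULL%02d", k))
    })
    users <- sample(seq_len(n), 12)
    recs$delta_age[users] <- recs$delta_age[users] - 6
    list(recs = recs, rx = dplyr::bind_rows(
      rx, tibble::tibble(participant_id = users, drug = "GEROPROT")))
  })
  scr <- screen_drugs(sim$rx, sim$recs)
  expect_equal(scr$drug[1], "GEROPROT")
  expect_lt(scr$median_shift[1], 0)
  # BH-adjusted p is monotone in the raw p
  expect_true(all(scr$adj_p >= scr$ks_p - 1e-12))
})

test_that("a fully null drug table rarely yields a BH-significant hit", {
  hits <- withr::with_seed(161, {
    vapply(1:40, function(rep) {
      n <- 400
      recs <- make_age_records(rep(75, n), rnorm(n, 0, 6))
      rx <- purrr::map_dfr(1:200, function(k) {
        tibble::tibble(participant_id = sample(seq_len(n), sample(5:40, 1)),
                       drug = sprintf("D%03d", k))
      })
      min(screen_drugs(rx, recs)$adj_p) < 0.05
    }, TRUE)
  })
  expect_lte(mean(hits), 0.10)
})
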