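# fixtures are generated in code and cached for the session
.actage_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.actage_cache[[key]])) assign(key, force(expr), envir = .actage_cache)
  get(key, envir = .actage_cache)
}

tiny_fixture <- function() cached("fixture", synth_fixture())

small_cohort <- function() {
  cached("small_cohort", synth_cohort(synth_config(n_participants = 250, seed = 11)))
}

# one complete activity week as a long tibble; `fill` is a scalar, a
# 10080-vector, or a function(day, minute) -> intensity
toy_week <- function(id = 1L, fill = 0L, calibrated = TRUE, days = 1:7) {
  grid <- expand.grid(minute = 0:1439, day = days)
  intensity <- if (is.function(fill)) {
    as.integer(fill(grid$day, grid$minute))
  } else {
    as.integer(rep_len(fill, nrow(grid)))
  }
  tibble::tibble(participant_id = id, calibrated = calibrated,
                 day = as.integer(grid$day), minute = as.integer(grid$minute),
                 intensity = intensity)
}

toy_demo <- function(ids, ages) {
  tibble::tibble(participant_id = ids, age_years = as.integer(ages))
}

# brute-force BH step-up oracle, independent of stats::p.adjust
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  ranked <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(ranked)))
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

# hand Pearson chi-square on a k x 2 table of (deaths, totals)
chisq_oracle <- function(deaths, totals) {
  alive <- totals - deaths
  tab <- cbind(deaths, alive)
  exp_tab <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - exp_tab)^2 / exp_tab)
}
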