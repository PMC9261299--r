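#' Classify aging rate from deltaAge quartiles
#'
#' Restricts to participants at or above `min_age` (60 by default, where
#' follow-up mortality is informative), computes the quartiles of `delta_age`
#' on that subset with linear-interpolation quantiles, and labels the top
#' quartile (`delta_age >= Q3`) accelerated, the bottom quartile (`<= Q1`)
#' decelerated, and the middle half normal. Ties at a cutpoint go to the
#' extreme class, so the extreme classes are never empty.
#'
#' @param data Tibble with `age_chron` and `delta_age`.
#' @param min_age Minimum chronological age for the analysis subset.
#' @return Tibble `participant_id` (if present), `age_chron`, `delta_age`,
#'   `aging_class` (factor decelerated/normal/accelerated), with the quartile
#'   cutpoints attached as attribute `"cutpoints"`.
#' @export
classify_aging <- function(data, min_age = 60) {
  sub <- data[data$age_chron >= min_age, , drop = FALSE]
  if (nrow(sub) < 8) abort_validation("need at least 8 participants above min_age")
  d <- sub$delta_age
  if (length(unique(d)) == 1) {
    abort_validation("degenerate distribution: all delta_ages identical")
  }
  q <- stats::quantile(d, c(0.25, 0.75), type = 7, names = FALSE)
  cls <- dplyr::case_when(
    d >= q[2] ~ "accelerated",
    d <= q[1] ~ "decelerated",
    TRUE ~ "normal"
  )
  sub$aging_class <- factor(cls, levels = c("decelerated", "normal", "accelerated"))
  attr(sub, "cutpoints") <- c(q1 = q[1], q3 = q[2])
  sub
}

#' Equality-of-proportions test of mortality across aging classes
#'
#' Tests whether the proportion of deceased participants differs across the
#' accelerated / normal / decelerated classes with a 3-sample test for
#' equality of proportions without continuity correction (a Pearson
#' chi-square on the implied 3 x 2 table, df = 2). Participants with unknown
#' vital status are excluded and counted.
#'
#' @param data Tibble with `aging_class` (from [classify_aging()]) and
#'   `vital_status` (`"alive"` / `"deceased"` / `"unknown"`).
#' @return One-row tibble: `statistic`, `df`, `p_value`,
#'   `prop_accelerated`, `prop_normal`, `prop_decelerated`, `n_used`,
#'   `n_unknown`, with the 3 x 2 table attached as attribute `"table"`.
#' @export
test_mortality_proportions <- function(data) {
  known <- data[data$vital_status %in% c("alive", "deceased"), , drop = FALSE]
  n_unknown <- nrow(data) - nrow(known)
  counts <- table(factor(known$aging_class,
                         levels = c("accelerated", "normal", "decelerated")),
                  factor(known$vital_status, levels = c("deceased", "alive")))
  totals <- rowSums(counts)
  if (any(totals == 0)) abort_validation("every aging class needs at least one member")
  deaths <- counts[, "deceased"]

  ht <- suppressWarnings(stats::prop.test(deaths, totals, correct = FALSE))
  props <- deaths / totals
  out <- tibble::tibble(
    statistic = unname(ht$statistic),
    df = unname(ht$parameter),
    p_value = ht$p.value,
    prop_accelerated = unname(props["accelerated"]),
    prop_normal = unname(props["normal"]),
    prop_decelerated = unname(props["decelerated"]),
    n_used = nrow(known),
    n_unknown = n_unknown
  )
  attr(out, "table") <- counts
  out
}

#' Per-decade comparison of deltaAge between deceased and alive
#'
#' Within each decade-of-life bin, compares the deltaAges of deceased vs
#' alive participants with a two-sample Student's t-test (equal variances by
#' default, matching the printed method; set `var_equal = FALSE` for Welch).
#' Bins with fewer than 2 members on either side are flagged untestable
#' rather than erroring.
#'
#' @param data Tibble with `age_chron`, `delta_age`, `vital_status`.
#' @param var_equal Pool variances (classic Student's t)? Default `TRUE`.
#' @return Tibble with one row per decade bin: `bin`, `n_alive`,
#'   `n_deceased`, `mean_alive`, `mean_deceased`, `statistic`, `p_value`,
#'   `testable`.
#' @export
test_mortality_by_decade <- function(data, var_equal = TRUE) {
  known <- data[data$vital_status %in% c("alive", "deceased"), , drop = FALSE]
  known$bin <- decade_of(known$age_chron)
  purrr::map_dfr(levels(known$bin), function(b) {
    rows <- known[!is.na(known$bin) & known$bin == b, , drop = FALSE]
    a <- rows$delta_age[rows$vital_status == "alive"]
    d <- rows$delta_age[rows$vital_status == "deceased"]
    base <- tibble::tibble(
      bin = b, n_alive = length(a), n_deceased = length(d),
      mean_alive = if (length(a)) mean(a) else NA_real_,
      mean_deceased = if (length(d)) mean(d) else NA_real_)
    if (length(a) < 2 || length(d) < 2 ||
        (stats::sd(c(a, d)) == 0)) {
      return(dplyr::mutate(base, statistic = NA_real_, p_value = NA_real_,
                           testable = FALSE))
    }
    ht <- stats::t.test(d, a, var.equal = var_equal)
    dplyr::mutate(base, statistic = unname(ht$statistic),
                  p_value = ht$p.value, testable = TRUE)
  })
}

#' Per-cause-of-death deltaAge shifts vs the alive group
#'
#' For each ICD-10 cause group among the deceased, compares deltaAge against
#' the alive group ("presumed alive": alive or no cause found) with a
#' two-sample Student's t-test, reporting the mean shift. Sorted by
#' descending shift, so causes most associated with accelerated aging come
#' first.
#'
#' @param data Tibble with `delta_age`, `vital_status`, `cause_group`.
#' @param var_equal Pool variances? Default `TRUE`.
#' @param min_n Minimum cause-group size to report (default 2).
#' @return Tibble: `cause_group`, `n`, `mean_shift`, `statistic`, `p_value`.
#' @export
test_mortality_by_cause <- function(data, var_equal = TRUE, min_n = 2) {
  alive <- data$delta_age[data$vital_status != "deceased" | is.na(data$cause_group)]
  dead <- data[data$vital_status == "deceased" & !is.na(data$cause_group), ,
               drop = FALSE]
  if (nrow(dead) == 0 || length(alive) < 2) {
    return(tibble::tibble(cause_group = character(0), n = integer(0),
                          mean_shift = numeric(0), statistic = numeric(0),
                          p_value = numeric(0)))
  }
  out <- purrr::map_dfr(split(dead$delta_age, dead$cause_group), function(d) {
    if (length(d) < min_n) return(NULL)
    ht <- stats::t.test(d, alive, var.equal = var_equal)
    tibble::tibble(n = length(d), mean_shift = mean(d) - mean(alive),
                   statistic = unname(ht$statistic), p_value = ht$p.value)
  }, .id = "cause_group")
  dplyr::arrange(out, dplyr::desc(.data$mean_shift))
}
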