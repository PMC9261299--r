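#' Decade-of-life bins
#'
#' The pipeline bins adult ages into half-open decade intervals
#' `[18,30), [30,40), ..., [70,80), [80,85+]`. The ordinal column follows the
#' everyday convention in which `[30,40)` is the "4th decade of life". The
#' first bin spans ages 18-29 (tail of the 2nd plus the 3rd decade) because
#' the cohort starts at 18.
#'
#' @return A tibble with columns `label`, `lower`, `upper` (half-open, the
#'   last bin closed at the 85+ top-code), and `ordinal`.
#' @export
decade_bins <- function() {
  tibble::tibble(
    label = c("18-29", "30-39", "40-49", "50-59", "60-69", "70-79", "80+"),
    lower = c(18, 30, 40, 50, 60, 70, 80),
    upper = c(30, 40, 50, 60, 70, 80, Inf),
    ordinal = c(3L, 4L, 5L, 6L, 7L, 8L, 9L)
  )
}

# integer index 1..7 into decade_bins() for each age (>= 18); NA below 18
decade_bin_index <- function(age) {
  idx <- findInterval(age, c(18, 30, 40, 50, 60, 70, 80))
  idx[age < 18] <- NA_integer_
  idx
}

#' Assign each age to its decade-of-life bin label
#'
#' @param age Numeric vector of ages in years (top-code 85 = "85+").
#' @return Factor with the levels of `decade_bins()$label`; `NA` below 18.
#' @export
decade_of <- function(age) {
  bins <- decade_bins()
  factor(bins$label[decade_bin_index(age)], levels = bins$label)
}
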