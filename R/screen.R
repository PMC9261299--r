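#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjusted p-values (monotone, capped at 1).
#' Input p-values must lie in (0, 1].
#'
#' @param p Numeric vector of p-values.
#' @return Adjusted p-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(!is.finite(p) | p <= 0 | p > 1)) {
    abort_validation("p-values must lie in (0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Nutrient screen: decade-binned correlation with deltaAge
#'
#' For every nutrient and every decade-of-life bin, computes the Pearson
#' product-moment correlation between daily intake and deltaAge, with its
#' p-value, across participants in that bin. Cells with fewer than 3
#' nonmissing intakes, or zero-variance intake, are left missing (never
#' imputed). Benjamini-Hochberg adjustment is applied across nutrients
#' within each bin by default (`bh_scope = "bin"`), or across all cells
#' (`"all"`).
#'
#' @param diet Tibble: `participant_id` plus one numeric column per nutrient
#'   code.
#' @param age_records Tibble with `participant_id`, `age_chron`, `delta_age`.
#' @param bh_scope `"bin"` (default) or `"all"`.
#' @return Tibble with one row per nutrient x bin: `nutrient`, `bin`, `n`,
#'   `r`, `p_value`, `adj_p`.
#' @export
screen_nutrients <- function(diet, age_records, bh_scope = c("bin", "all")) {
  bh_scope <- match.arg(bh_scope)
  merged <- dplyr::inner_join(age_records, diet, by = "participant_id")
  merged$bin <- decade_of(merged$age_chron)
  nutrients <- setdiff(names(diet), "participant_id")

  grid <- tidyr::expand_grid(nutrient = nutrients,
                             bin = levels(merged$bin))
  res <- purrr::pmap_dfr(grid, function(nutrient, bin) {
    rows <- merged[!is.na(merged$bin) & merged$bin == bin, , drop = FALSE]
    x <- rows[[nutrient]]
    d <- rows$delta_age
    ok <- is.finite(x) & is.finite(d)
    x <- x[ok]; d <- d[ok]
    if (length(x) < 3 || stats::sd(x) == 0 || stats::sd(d) == 0) {
      return(tibble::tibble(nutrient = nutrient, bin = bin, n = length(x),
                            r = NA_real_, p_value = NA_real_))
    }
    ht <- stats::cor.test(x, d, method = "pearson")
    tibble::tibble(nutrient = nutrient, bin = bin, n = length(x),
                   r = unname(ht$estimate), p_value = ht$p.value)
  })

  res$adj_p <- NA_real_
  clamp <- function(p) pmax(p, .Machine$double.xmin)  # r = +/-1 gives p = 0
  if (bh_scope == "bin") {
    for (b in unique(res$bin)) {
      sel <- res$bin == b & !is.na(res$p_value)
      res$adj_p[sel] <- bh_adjust(clamp(res$p_value[sel]))
    }
  } else {
    sel <- !is.na(res$p_value)
    res$adj_p[sel] <- bh_adjust(clamp(res$p_value[sel]))
  }
  res$bin <- factor(res$bin, levels = decade_bins()$label)
  res
}

#' Cluster nutrient correlation profiles
#'
#' Rows are nutrients, columns their per-decade correlation with deltaAge;
#' profiles are clustered by agglomerative hierarchical clustering on
#' Euclidean distance (complete linkage) and cut into `k` clusters. Nutrients
#' with any missing cell are dropped and reported via the
#' `"dropped"` attribute.
#'
#' @param nutrient_screen Output of [screen_nutrients()].
#' @param k Number of clusters (default 5).
#' @return Tibble `nutrient`, `cluster`, `dendro_order`, with attributes
#'   `"hclust"` (the tree), `"profiles"` (the matrix clustered) and
#'   `"dropped"`.
#' @export
cluster_nutrients <- function(nutrient_screen, k = 5) {
  wide <- tidyr::pivot_wider(
    nutrient_screen[, c("nutrient", "bin", "r")],
    names_from = "bin", values_from = "r")
  mat <- as.matrix(wide[, -1, drop = FALSE])
  rownames(mat) <- wide$nutrient
  complete <- stats::complete.cases(mat)
  dropped <- rownames(mat)[!complete]
  if (length(dropped) > 0) {
    rlang::inform(sprintf("cluster_nutrients: dropped %d nutrient(s) with missing cells",
                          length(dropped)))
  }
  mat <- mat[complete, , drop = FALSE]
  if (nrow(mat) < k) {
    rlang::abort("fewer complete nutrient profiles than clusters k",
                 class = "actage_parameter_error")
  }
  hc <- stats::hclust(stats::dist(mat, method = "euclidean"), method = "complete")
  cl <- stats::cutree(hc, k = k)
  out <- tibble::tibble(
    nutrient = rownames(mat),
    cluster = unname(cl),
    dendro_order = match(rownames(mat), rownames(mat)[hc$order])
  )
  attr(out, "hclust") <- hc
  attr(out, "profiles") <- mat
  attr(out, "dropped") <- dropped
  out
}

#' Extreme-deltaAge comparison of a nutrient's intake
#'
#' Compares intake of one nutrient between the strongly decelerated
#' (`delta_age < -cut`) and strongly accelerated (`delta_age > +cut`) groups
#' with a two-sample Student's t-test. With fewer than 2 participants in
#' either extreme the comparison is flagged untestable.
#'
#' @param diet Tibble: `participant_id` + nutrient columns.
#' @param age_records Tibble with `participant_id`, `delta_age`.
#' @param nutrient Nutrient column name.
#' @param cut Extreme threshold in years (default 10).
#' @param var_equal Pool variances? Default `TRUE`.
#' @return One-row tibble: `nutrient`, `n_decelerated`, `n_accelerated`,
#'   `mean_decelerated`, `mean_accelerated`, `statistic`, `p_value`,
#'   `testable`.
#' @export
test_extreme_groups <- function(diet, age_records, nutrient, cut = 10,
                                var_equal = TRUE) {
  if (!nutrient %in% names(diet)) {
    abort_schema(sprintf("nutrient column `%s` not found", nutrient))
  }
  merged <- dplyr::inner_join(age_records, diet[, c("participant_id", nutrient)],
                              by = "participant_id")
  lo <- merged[[nutrient]][merged$delta_age < -cut]
  hi <- merged[[nutrient]][merged$delta_age > cut]
  lo <- lo[is.finite(lo)]; hi <- hi[is.finite(hi)]
  base <- tibble::tibble(
    nutrient = nutrient, n_decelerated = length(lo), n_accelerated = length(hi),
    mean_decelerated = if (length(lo)) mean(lo) else NA_real_,
    mean_accelerated = if (length(hi)) mean(hi) else NA_real_)
  if (length(lo) < 2 || length(hi) < 2 || stats::sd(c(lo, hi)) == 0) {
    return(dplyr::mutate(base, statistic = NA_real_, p_value = NA_real_,
                         testable = FALSE))
  }
  ht <- stats::t.test(lo, hi, var.equal = var_equal)
  dplyr::mutate(base, statistic = unname(ht$statistic), p_value = ht$p.value,
                testable = TRUE)
}

#' Drug screen: Kolmogorov-Smirnov test of users' deltaAges
#'
#' Restricts to the advanced-age subset (`age_chron >= min_age`, 70 by
#' default, the 85+ top-code included) and, for every drug with at least one
#' user there, compares the deltaAge distribution of users against the
#' comparison population with a two-sample Kolmogorov-Smirnov test. The
#' default comparison population is *all* participants in the subset, users
#' included (conservative, as the method is usually stated); set
#' `comparison = "nonusers"` for a users-vs-nonusers contrast. Each
#' participant contributes their deltaAge once per distinct drug they use.
#'
#' The rank score is `log10(p) * sign(median_shift)`; since `log10(p) < 0`,
#' *decelerating* drugs (negative median shift) receive *positive* scores, so
#' "most decelerating" sorts by descending `rank_score`.
#'
#' @param rx Long tibble `participant_id`, `drug` (one row per prescription;
#'   duplicates collapse).
#' @param age_records Tibble with `participant_id`, `age_chron`, `delta_age`.
#' @param min_age Minimum age of the screened subset (default 70).
#' @param comparison `"all"` (default) or `"nonusers"`.
#' @param min_users Drop drugs with fewer users than this (default 1).
#' @return Tibble, one row per drug, sorted by descending `rank_score`:
#'   `drug`, `n_users`, `median_shift` (median user deltaAge minus median
#'   comparison deltaAge, years), `ks_p`, `adj_p`, `rank_score`.
#' @export
screen_drugs <- function(rx, age_records, min_age = 70,
                         comparison = c("all", "nonusers"), min_users = 1) {
  comparison <- match.arg(comparison)
  sub <- age_records[age_records$age_chron >= min_age, , drop = FALSE]
  if (nrow(sub) == 0) abort_validation("empty subset: no participants at min_age")

  users <- dplyr::distinct(rx[rx$participant_id %in% sub$participant_id,
                              c("participant_id", "drug")])
  if (nrow(users) == 0) {
    return(tibble::tibble(drug = character(0), n_users = integer(0),
                          median_shift = numeric(0), ks_p = numeric(0),
                          adj_p = numeric(0), rank_score = numeric(0)))
  }
  delta_of <- stats::setNames(sub$delta_age, sub$participant_id)
  all_delta <- sub$delta_age

  res <- purrr::map_dfr(split(users$participant_id, users$drug), function(uid) {
    ud <- unname(delta_of[as.character(uid)])
    if (length(ud) < min_users) return(NULL)
    comp <- if (comparison == "all") all_delta else {
      sub$delta_age[!sub$participant_id %in% uid]
    }
    ht <- suppressWarnings(stats::ks.test(ud, comp, exact = FALSE))
    tibble::tibble(n_users = length(ud),
                   median_shift = stats::median(ud) - stats::median(comp),
                   ks_p = ht$p.value)
  }, .id = "drug")
  if (nrow(res) == 0) {
    return(tibble::tibble(drug = character(0), n_users = integer(0),
                          median_shift = numeric(0), ks_p = numeric(0),
                          adj_p = numeric(0), rank_score = numeric(0)))
  }
  res$ks_p <- pmin(pmax(res$ks_p, .Machine$double.xmin), 1)
  res$adj_p <- bh_adjust(res$ks_p)
  res$rank_score <- log10(res$ks_p) * sign(res$median_shift)
  dplyr::arrange(res, dplyr::desc(.data$rank_score))
}
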