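#' Clinical-threshold subgroup labels
#'
#' The five strata of predicted differential glycaemic benefit, ordered
#' from most SGLT2i-favoured to most DPP4i-favoured.
#'
#' @return Character vector of the five labels.
#' @export
subgroup_levels <- function() {
  c("SGLT2i benefit >=5", "SGLT2i benefit 3-5", "SGLT2i benefit 0-3",
    "DPP4i benefit 0-3", "DPP4i benefit >=3")
}

#' Assign clinically relevant benefit subgroups
#'
#' Maps each predicted SGLT2i - DPP4i difference (mmol/mol; negative =
#' SGLT2i benefit) to one of five strata:
#' `diff <= -5` -> SGLT2i benefit >=5; `-5 < diff <= -3` -> SGLT2i benefit
#' 3-5; `-3 < diff <= 0` -> SGLT2i benefit 0-3; `0 < diff < 3` -> DPP4i
#' benefit 0-3; `diff >= 3` -> DPP4i benefit >=3.
#'
#' Boundary convention: interval endpoints belong to the stronger-benefit
#' side (so -5 and -3 go outward on the SGLT2i side, +3 outward on the
#' DPP4i side) and a difference of exactly 0 counts as SGLT2i benefit 0-3.
#' This makes the five labels a partition of the real line.
#'
#' @param diff Numeric vector of predicted differences, mmol/mol.
#' @return Factor with levels [subgroup_levels()].
#' @export
assign_subgroup <- function(diff) {
  if (any(!is.finite(diff))) stop("`diff` must be finite", call. = FALSE)
  lv <- subgroup_levels()
  lab <- ifelse(diff <= -5, lv[1],
         ifelse(diff <= -3, lv[2],
         ifelse(diff <= 0,  lv[3],
         ifelse(diff < 3,   lv[4], lv[5]))))
  factor(lab, levels = lv)
}

#' Wilson score confidence interval for a proportion
#'
#' @param x Number of events.
#' @param n Number of trials.
#' @param conf_level Confidence level.
#' @return Numeric vector `c(low, high)`.
#' @export
wilson_ci <- function(x, n, conf_level = 0.95) {
  if (n == 0) return(c(NA_real_, NA_real_))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  p <- x / n
  centre <- (p + z^2 / (2 * n)) / (1 + z^2 / n)
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
  c(max(0, centre - half), min(1, centre + half))
}

t_ci <- function(x, conf_level = 0.95) {
  n <- length(x)
  if (n < 2 || stats::sd(x) == 0) return(c(NA_real_, NA_real_))
  m <- mean(x)
  half <- stats::qt(1 - (1 - conf_level) / 2, df = n - 1) * stats::sd(x) / sqrt(n)
  c(m - half, m + half)
}

#' Unadjusted outcome summaries by benefit subgroup and drug
#'
#' For each (subgroup, drug) cell: unadjusted mean glycaemic response
#' (outcome minus baseline HbA1c; negative = improvement) with a
#' t-interval, unadjusted mean 6-month weight change with a t-interval, and
#' the proportion discontinuing within 6 months with a Wilson interval.
#' Also reports each subgroup's share of the cohort. Cells absent from the
#' data are emitted with `n = 0` and `NA` estimates.
#'
#' @param rows Built-cohort rows (need `outcome_hba1c`, `baseline_hba1c`,
#'   `weight_change`, `discontinued`, `drug`).
#' @param pred_diff Updated predicted differences aligned with `rows`.
#' @param conf_level Confidence level for all intervals.
#' @return Tibble keyed by `subgroup` x `drug` with counts, proportions and
#'   interval-bounded summaries.
#' @export
subgroup_summary <- function(rows, pred_diff, conf_level = 0.95) {
  rows <- tibble::as_tibble(rows)
  if (length(pred_diff) != nrow(rows)) {
    stop("`pred_diff` must align with `rows`", call. = FALSE)
  }
  rows$subgroup <- assign_subgroup(pred_diff)
  rows$response <- rows$outcome_hba1c - rows$baseline_hba1c
  n_total <- nrow(rows)
  sub_n <- table(rows$subgroup)

  grid <- tidyr::expand_grid(subgroup = factor(subgroup_levels(),
                                               levels = subgroup_levels()),
                             drug = drug_levels())
  purrr::pmap_dfr(grid, function(subgroup, drug) {
    cell <- rows[rows$subgroup == subgroup & rows$drug == drug, ]
    n <- nrow(cell)
    if (n == 0) {
      return(tibble::tibble(
        subgroup = as.character(subgroup), drug = drug, n = 0L,
        subgroup_prop = unname(sub_n[as.character(subgroup)]) / max(n_total, 1L),
        mean_response = NA_real_, response_ci_low = NA_real_,
        response_ci_high = NA_real_, mean_weight_change = NA_real_,
        weight_ci_low = NA_real_, weight_ci_high = NA_real_,
        discontinuation = NA_real_, disc_ci_low = NA_real_,
        disc_ci_high = NA_real_))
    }
    rci <- t_ci(cell$response, conf_level)
    wci <- t_ci(cell$weight_change, conf_level)
    disc <- sum(cell$discontinued)
    dci <- wilson_ci(disc, n, conf_level)
    tibble::tibble(
      subgroup = as.character(subgroup), drug = drug, n = n,
      subgroup_prop = unname(sub_n[as.character(subgroup)]) / n_total,
      mean_response = mean(cell$response),
      response_ci_low = rci[1], response_ci_high = rci[2],
      mean_weight_change = mean(cell$weight_change),
      weight_ci_low = wci[1], weight_ci_high = wci[2],
      discontinuation = disc / n,
      disc_ci_low = dci[1], disc_ci_high = dci[2])
  })
}
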