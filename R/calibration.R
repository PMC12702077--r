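#' Assign deciles of predicted treatment-effect difference
#'
#' Groups rows into ten bins by the empirical deciles (type-7 quantiles) of
#' their predicted SGLT2i - DPP4i differences. The assignment is monotone
#' in the difference; values equal to an interior cut point fall into the
#' lower decile, so heavy ties collapse into lower bins (a warning is
#' emitted when ties make fewer than ten distinct bins possible). With `n`
#' divisible by 10 and all-distinct values the bins are exactly equal-sized.
#'
#' @param diffs Numeric vector of predicted differences (>= 10 values).
#' @return Integer vector of decile indices, 1 (most SGLT2i-favoured) to 10.
#' @export
assign_deciles <- function(diffs) {
  if (length(diffs) < 10L) {
    stop("need at least 10 rows to form deciles", call. = FALSE)
  }
  if (anyNA(diffs)) stop("`diffs` must be complete", call. = FALSE)
  cuts <- stats::quantile(diffs, probs = seq(0.1, 0.9, by = 0.1), type = 7, names = FALSE)
  cuts <- unique(cuts)
  if (length(cuts) < 9L) {
    warning("tied predicted differences: fewer than 10 distinct deciles", call. = FALSE)
  }
  findInterval(diffs, cuts, left.open = TRUE) + 1L
}

pick_knots <- function(x) {
  k <- stats::quantile(x, probs = c(0.1, 0.5, 0.9), type = 7, names = FALSE)
  if (anyDuplicated(k) || any(diff(k) <= 0)) return(NULL)
  k
}

# Design matrix for the covariate-adjusted arm contrast. Continuous
# covariates enter as 3-knot RCS at within-subset 10/50/90th percentiles
# (dropping to linear when knots collide, and out entirely when constant);
# drug-count covariates enter as categorical levels; IMD optionally as
# categorical.
adjustment_design <- function(rows, adjust_imd = FALSE, spline_month = TRUE) {
  n <- nrow(rows)
  X <- list(`(Intercept)` = rep(1, n),
            drug_sglt2i = as.numeric(rows$drug == "SGLT2i"))
  continuous <- c("baseline_hba1c", "outcome_month", "egfr", "log_alt", "age", "bmi")
  for (f in continuous) {
    x <- rows[[f]]
    if (length(unique(x)) <= 1L) next
    use_spline <- if (f == "outcome_month") spline_month else TRUE
    k <- if (use_spline) pick_knots(x) else NULL
    if (is.null(k)) {
      X[[paste0(f, "_lin")]] <- x
    } else {
      B <- rcs_basis(x, k)
      X[[paste0(f, "_lin")]] <- B[, 1L]
      X[[paste0(f, "_rcs")]] <- B[, 2L]
    }
  }
  for (f in c("n_current_drugs", "n_ever_classes", if (adjust_imd) "imd_quintile")) {
    v <- factor(rows[[f]])
    if (nlevels(v) <= 1L) next
    M <- stats::model.matrix(~v)[, -1L, drop = FALSE]
    colnames(M) <- paste0(f, "_", levels(v)[-1L])
    for (j in seq_len(ncol(M))) X[[colnames(M)[j]]] <- M[, j]
  }
  do.call(cbind, X)
}

#' Covariate-adjusted observed arm difference in outcome HbA1c
#'
#' Estimates the average difference in achieved 6-month HbA1c between
#' SGLT2i and DPP4i initiators from an OLS model with achieved HbA1c as
#' outcome, received drug class as the main effect, and adjustment for
#' baseline HbA1c, number of other current glucose-lowering drugs, number
#' of glucose-lowering drug classes ever prescribed, month of the outcome
#' measurement, eGFR, log-ALT, current age and baseline BMI (continuous
#' covariates as 3-knot restricted cubic splines with knots at the
#' within-subset 10/50/90th percentiles; drug-count covariates as
#' categorical levels). The adjustment accounts for the arms not being
#' matched (confounding by indication).
#'
#' @param rows Built-cohort rows containing both drugs.
#' @param adjust_imd Also adjust for IMD quintile (categorical); rows with
#'   missing IMD are dropped from this fit only.
#' @param spline_month Spline the outcome-month covariate (default) or
#'   enter it linearly.
#' @param conf_level Confidence level for the Wald interval.
#' @return One-row tibble: `estimate` (SGLT2i minus DPP4i, mmol/mol), `se`,
#'   `ci_low`, `ci_high`, `n_sglt2i`, `n_dpp4i`.
#' @export
adjusted_arm_difference <- function(rows, adjust_imd = FALSE, spline_month = TRUE,
                                    conf_level = 0.95) {
  rows <- tibble::as_tibble(rows)
  if (adjust_imd) rows <- rows[!is.na(rows$imd_quintile), ]
  n_s <- sum(rows$drug == "SGLT2i")
  n_d <- sum(rows$drug == "DPP4i")
  if (n_s == 0 || n_d == 0) {
    stop("both drug classes must be present to estimate an arm difference", call. = FALSE)
  }
  X <- adjustment_design(rows, adjust_imd = adjust_imd, spline_month = spline_month)
  if (nrow(X) <= ncol(X)) {
    stop("too few rows (", nrow(X), ") for ", ncol(X), " adjustment parameters",
         call. = FALSE)
  }
  df <- as.data.frame(X[, -1L, drop = FALSE])
  df$.y <- rows$outcome_hba1c
  fit <- stats::lm(.y ~ ., data = df)
  co <- stats::coef(fit)
  if (anyNA(co)) stop("degenerate adjustment design (rank deficient)", call. = FALSE)
  sm <- summary(fit)$coefficients
  est <- sm["drug_sglt2i", "Estimate"]
  se <- sm["drug_sglt2i", "Std. Error"]
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  tibble::tibble(estimate = est, se = se,
                 ci_low = est - z * se, ci_high = est + z * se,
                 n_sglt2i = n_s, n_dpp4i = n_d)
}

#' Decile-level calibration of predicted differential treatment effects
#'
#' Within each decile of (updated) predicted SGLT2i - DPP4i difference,
#' compares the mean predicted difference to the covariate-adjusted
#' observed arm difference with its 95% confidence interval. A
#' well-calibrated model has the observed contrasts tracking the predicted
#' means along the identity line.
#'
#' @param rows Built-cohort rows.
#' @param pred_diff Numeric vector aligned with `rows`: updated predicted
#'   differences (after any recalibration of each arm's predictions).
#' @inheritParams adjusted_arm_difference
#' @return Tibble with one row per decile: `decile`, `n_sglt2i`,
#'   `n_dpp4i`, `mean_pred_diff`, `adj_obs_diff`, `se`, `ci_low`,
#'   `ci_high`.
#' @export
calibration_table <- function(rows, pred_diff, adjust_imd = FALSE,
                              spline_month = TRUE) {
  rows <- tibble::as_tibble(rows)
  if (length(pred_diff) != nrow(rows)) {
    stop("`pred_diff` must align with `rows`", call. = FALSE)
  }
  dec <- assign_deciles(pred_diff)
  purrr::map_dfr(sort(unique(dec)), function(d) {
    idx <- dec == d
    arm <- adjusted_arm_difference(rows[idx, ], adjust_imd = adjust_imd,
                                   spline_month = spline_month)
    tibble::tibble(decile = d,
                   n_sglt2i = arm$n_sglt2i, n_dpp4i = arm$n_dpp4i,
                   mean_pred_diff = mean(pred_diff[idx]),
                   adj_obs_diff = arm$estimate, se = arm$se,
                   ci_low = arm$ci_low, ci_high = arm$ci_high)
  })
}

#' Root mean squared prediction error
#'
#' @param obs Observed values.
#' @param pred Predicted values.
#' @return `sqrt(mean((obs - pred)^2))`, on the outcome scale.
#' @export
rmse <- function(obs, pred) {
  check_obs_pred(obs, pred, min_n = 1L)
  sqrt(mean((obs - pred)^2))
}
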