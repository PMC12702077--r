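#' Intercept-only recalibration (recalibration-in-the-large)
#'
#' Fits the intercept-only linear regression with the difference between
#' observed and predicted HbA1c as the outcome. Its OLS solution is the
#' arithmetic mean of `obs - pred`: the average amount by which observed
#' outcomes undershoot (negative) or overshoot (positive) the model's
#' predictions.
#'
#' @param obs Observed outcome HbA1c, mmol/mol.
#' @param pred Predicted HbA1c from the model under evaluation, mmol/mol.
#' @return The updated intercept `a`, mmol/mol.
#' @export
model2_intercept <- function(obs, pred) {
  check_obs_pred(obs, pred, min_n = 1L)
  mean(obs - pred)
}

#' Intercept-and-slope recalibration
#'
#' OLS regression of the observed HbA1c outcome on the predicted HbA1c
#' outcome from the model under evaluation; returns the fitted intercept
#' and calibration slope.
#'
#' @inheritParams model2_intercept
#' @return Named numeric vector `c(a =, b =)`.
#' @export
model3_fit <- function(obs, pred) {
  check_obs_pred(obs, pred, min_n = 2L)
  if (stats::sd(pred) == 0) {
    stop("predictions are constant: slope recalibration is degenerate", call. = FALSE)
  }
  fit <- stats::lm(obs ~ pred)
  co <- stats::coef(fit)
  c(a = unname(co[1]), b = unname(co[2]))
}

check_obs_pred <- function(obs, pred, min_n) {
  if (length(obs) != length(pred)) stop("obs and pred lengths differ", call. = FALSE)
  if (length(obs) < min_n) stop("need at least ", min_n, " observations", call. = FALSE)
  if (anyNA(obs) || anyNA(pred)) stop("obs and pred must be complete", call. = FALSE)
  invisible(TRUE)
}

#' Profile Gaussian log-likelihood of a set of predictions
#'
#' Log-likelihood of `obs` under a Gaussian model centred at
#' `pred_adjusted`, with the variance profiled out at its maximum-likelihood
#' value RSS/n:
#' `LL = -(n/2) * (log(2*pi) + log(RSS/n) + 1)`.
#' This is the likelihood the closed testing procedure compares across
#' nested recalibration models.
#'
#' @param obs Observed outcomes.
#' @param pred_adjusted Model predictions after any recalibration.
#' @return Scalar log-likelihood.
#' @export
gaussian_loglik <- function(obs, pred_adjusted) {
  check_obs_pred(obs, pred_adjusted, min_n = 2L)
  n <- length(obs)
  rss <- sum((obs - pred_adjusted)^2)
  if (rss <= 0) stop("zero residual variance: log-likelihood is degenerate", call. = FALSE)
  -(n / 2) * (log(2 * pi) + log(rss / n) + 1)
}

#' Closed testing procedure for model updating
#'
#' Decides between keeping the original model (Model 1), updating its
#' intercept (Model 2, recalibration-in-the-large) or updating intercept
#' and calibration slope (Model 3), using a sequence of likelihood-ratio
#' tests on the profile Gaussian log-likelihood:
#'
#' * `ll1`: predictions used as-is;
#' * `ll2`: after the Model 2 intercept update;
#' * `ll3`: after the Model 3 intercept + slope update;
#' * test 1: `lr1 = 2 (ll2 - ll1)`, Model 2 versus Model 1;
#' * test 2: `lr2 = 2 (ll3 - ll2)`, Model 3 versus Model 2.
#'
#' Decision rules at level `alpha`: if test 2 is significant choose Model 3;
#' otherwise if test 1 is significant choose Model 2; otherwise keep
#' Model 1.
#'
#' Two degrees-of-freedom conventions are supported. `"literal"` (default)
#' uses `df = m` for test 1 and `df = m + 1` for test 2, where `m` is the
#' number of estimated non-intercept parameters of the original model (see
#' [n_model_params()]); with realistic `m` this makes the tests deliberately
#' conservative. `"nesting"` uses `df = 1` for both tests -- the parameter
#' count actually separating the nested recalibration models -- under which
#' the likelihood-ratio statistics have their asymptotic chi-square(1) null
#' distribution and the tests reject at the nominal rate. See the package
#' vignette for the trade-off.
#'
#' @inheritParams model2_intercept
#' @param m Number of estimated non-intercept parameters in the original
#'   model.
#' @param alpha Significance level (default 0.05).
#' @param df_convention `"literal"` or `"nesting"`.
#' @param ethnicity,drug Optional labels carried into the decision.
#' @return An object of class `recal_decision`: the chosen model, the
#'   update coefficients `a` (intercept) and `b` (slope; `(a, b) = (0, 1)`
#'   for Model 1, `b = 1` for Model 2), log-likelihoods, LR statistics,
#'   p-values, `m`, `alpha`, degrees of freedom and `n`.
#' @export
closed_test <- function(obs, pred, m, alpha = 0.05,
                        df_convention = c("literal", "nesting"),
                        ethnicity = NA_character_, drug = NA_character_) {
  df_convention <- match.arg(df_convention)
  if (!is.numeric(m) || length(m) != 1L || m < 1 || m != floor(m)) {
    stop("`m` must be a positive integer", call. = FALSE)
  }
  if (alpha <= 0 || alpha >= 1) stop("`alpha` must be in (0, 1)", call. = FALSE)
  n <- length(obs)
  if (n <= m + 2) stop("need n > m + 2 observations for the closed test", call. = FALSE)
  check_obs_pred(obs, pred, min_n = 2L)

  a2 <- model2_intercept(obs, pred)
  m3 <- tryCatch(model3_fit(obs, pred), error = function(e) NULL)
  ll1 <- gaussian_loglik(obs, pred)
  ll2 <- gaussian_loglik(obs, pred + a2)
  ll3 <- if (is.null(m3)) ll2 else gaussian_loglik(obs, m3[["a"]] + m3[["b"]] * pred)

  df1 <- if (df_convention == "literal") m else 1
  df2 <- if (df_convention == "literal") m + 1 else 1
  lr1 <- 2 * (ll2 - ll1)
  lr2 <- 2 * (ll3 - ll2)
  p1 <- stats::pchisq(lr1, df = df1, lower.tail = FALSE)
  p2 <- stats::pchisq(lr2, df = df2, lower.tail = FALSE)

  if (!is.null(m3) && p2 < alpha) {
    chosen <- "Model3"; a <- m3[["a"]]; b <- m3[["b"]]
  } else if (p1 < alpha) {
    chosen <- "Model2"; a <- a2; b <- 1
  } else {
    chosen <- "Model1"; a <- 0; b <- 1
  }

  structure(
    list(ethnicity = ethnicity, drug = drug, chosen = chosen, a = a, b = b,
         ll1 = ll1, ll2 = ll2, ll3 = ll3, lr1 = lr1, lr2 = lr2,
         p1 = p1, p2 = p2, m = as.integer(m), alpha = alpha,
         df1 = df1, df2 = df2, df_convention = df_convention, n = n),
    class = "recal_decision"
  )
}

#' @export
print.recal_decision <- function(x, ...) {
  lab <- if (is.na(x$ethnicity)) "" else paste0(" [", x$ethnicity, " / ", x$drug, "]")
  cat("<recal_decision>", lab, "\n", sep = "")
  cat("  chosen:", x$chosen,
      sprintf("(a = %.3f, b = %.3f)", x$a, x$b), "\n")
  cat(sprintf("  test 1 (Model 2 vs 1): LR = %.3f, df = %d, p = %.4g\n",
              x$lr1, x$df1, x$p1))
  cat(sprintf("  test 2 (Model 3 vs 2): LR = %.3f, df = %d, p = %.4g\n",
              x$lr2, x$df2, x$p2))
  cat("  n =", x$n, " m =", x$m, " alpha =", x$alpha, "\n")
  invisible(x)
}

#' Tidy a closed-test decision
#'
#' @param x A `recal_decision` from [closed_test()].
#' @param ... Unused.
#' @return One-row tibble with the decision, update coefficients and all
#'   test statistics at full precision.
#' @export
tidy.recal_decision <- function(x, ...) {
  tibble::tibble(
    ethnicity = x$ethnicity, drug = x$drug, chosen = x$chosen,
    a = x$a, b = x$b, ll1 = x$ll1, ll2 = x$ll2, ll3 = x$ll3,
    lr1 = x$lr1, lr2 = x$lr2, p1 = x$p1, p2 = x$p2,
    df1 = x$df1, df2 = x$df2, m = x$m, alpha = x$alpha, n = x$n
  )
}

#' @rdname tidy.recal_decision
#' @export
glance.recal_decision <- function(x, ...) {
  tibble::tibble(chosen = x$chosen, a = x$a, b = x$b,
                 p1 = x$p1, p2 = x$p2, n = x$n)
}

#' Apply a recalibration update to predictions
#'
#' Element-wise `a + b * pred`. A Model 1 decision (`a = 0`, `b = 1`) is the
#' identity; Model 2 shifts every prediction by its intercept update.
#'
#' @param pred Numeric predictions.
#' @param decision A `recal_decision`, or anything with numeric elements
#'   `a` and `b`.
#' @return Updated predictions.
#' @export
apply_update <- function(pred, decision) {
  a <- decision$a
  b <- decision$b
  stopifnot(is.numeric(a), is.numeric(b), length(a) == 1L, length(b) == 1L)
  a + b * pred
}

#' Run the closed testing procedure per (ethnicity group, drug) cell
#'
#' Splits a built cohort by analysis ethnicity group and received drug,
#' evaluates the model under each cell's received drug, and runs
#' [closed_test()] on observed versus predicted outcome HbA1c. Cells below
#' `min_n` rows are skipped with a warning (the guard keeps the likelihood
#' machinery away from tiny cells; it is a pragmatic default, not a
#' clinical rule).
#'
#' @param cohort A built cohort (see [build_cohort()]) with
#'   `outcome_hba1c`.
#' @param spec The [model_spec()] under validation.
#' @param alpha Significance level.
#' @param df_convention See [closed_test()].
#' @param pool_mixed_other Pool Mixed and Other ethnicities?
#' @param min_n Minimum rows per cell.
#' @return Tibble with one tidy decision row per retained cell.
#' @export
recalibrate_cohort <- function(cohort, spec, alpha = 0.05,
                               df_convention = c("literal", "nesting"),
                               pool_mixed_other = TRUE, min_n = 100) {
  df_convention <- match.arg(df_convention)
  stopifnot(inherits(spec, "model_spec"))
  cohort <- tibble::as_tibble(cohort)
  m <- n_model_params(spec)
  cohort$.group <- ethnicity_group(cohort$ethnicity, pool_mixed_other)
  cells <- expand.grid(group = ethnicity_groups(pool_mixed_other), drug = drug_levels(),
                       stringsAsFactors = FALSE)
  out <- purrr::pmap(cells, function(group, drug) {
    rows <- cohort[cohort$.group == group & cohort$drug == drug, ]
    if (nrow(rows) < min_n) {
      warning(sprintf("cell %s / %s has %d rows (< %d): skipped",
                      group, drug, nrow(rows), min_n), call. = FALSE)
      return(NULL)
    }
    pred <- predict_outcome(spec, rows, drug)
    tidy(closed_test(rows$outcome_hba1c, pred, m = m, alpha = alpha,
                     df_convention = df_convention,
                     ethnicity = group, drug = drug))
  })
  dplyr::bind_rows(out)
}
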