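#' Configuration for a full validation run
#'
#' Collects every option of the three-step per-ethnicity validation:
#' input mode (synthetic generation or a cohort CSV), the model under
#' validation, the significance level and degrees-of-freedom convention of
#' the closed testing procedure, the outcome target month (6 for the
#' primary analysis, 12 for the longer-term sensitivity outcome), whether
#' Mixed and Other are pooled, whether the arm contrasts additionally
#' adjust for IMD quintile, and the minimum cell size guard.
#'
#' @param sim A [sim_config()] (synthetic mode), or `NULL` when reading a
#'   cohort from `cohort_file`.
#' @param cohort_file Path to a cohort CSV (see [read_cohort_csv()]);
#'   ignored when `sim` is given.
#' @param model The [model_spec()] under validation; defaults to the truth
#'   model of `sim` when available (the self-validation scenario), else to
#'   [default_model_spec()].
#' @param alpha Significance level of the closed testing procedure.
#' @param df_convention `"literal"` or `"nesting"`; see [closed_test()].
#' @param target_month Outcome target month, inside the window.
#' @param pool_mixed_other Pool Mixed and Other into one analysis group?
#' @param adjust_imd Add IMD quintile to the arm-contrast adjustment set?
#' @param spline_month Spline the outcome-month adjustment covariate?
#' @param min_n Minimum rows per (ethnicity group, drug) cell.
#' @return A list of class `run_config`.
#' @export
run_config <- function(sim = sim_config(), cohort_file = NULL, model = NULL,
                       alpha = 0.05, df_convention = c("literal", "nesting"),
                       target_month = 6, pool_mixed_other = TRUE,
                       adjust_imd = FALSE, spline_month = TRUE, min_n = 100) {
  df_convention <- match.arg(df_convention)
  if (is.null(sim) && is.null(cohort_file)) {
    stop("supply either `sim` or `cohort_file`", call. = FALSE)
  }
  if (alpha <= 0 || alpha >= 1) stop("`alpha` must be in (0, 1)", call. = FALSE)
  if (is.null(model)) {
    model <- if (!is.null(sim)) sim$truth_model else default_model_spec()
  }
  stopifnot(inherits(model, "model_spec"))
  window <- if (!is.null(sim)) sim$outcome_window else c(3, 15)
  if (target_month < window[1] || target_month > window[2]) {
    stop("`target_month` must lie inside the outcome window", call. = FALSE)
  }
  structure(list(sim = sim, cohort_file = cohort_file, model = model,
                 alpha = alpha, df_convention = df_convention,
                 target_month = target_month, window = window,
                 pool_mixed_other = pool_mixed_other, adjust_imd = adjust_imd,
                 spline_month = spline_month, min_n = min_n),
            class = "run_config")
}

#' Mean predicted benefit with confidence interval
#'
#' Mean of the (updated) predicted SGLT2i - DPP4i differences with a
#' t-interval. A negative mean is an average predicted HbA1c benefit on
#' SGLT2i of that magnitude. Constant differences yield a degenerate
#' (zero-width) interval, flagged with a warning.
#'
#' @param diffs Numeric vector of predicted differences (length >= 2).
#' @param conf_level Confidence level.
#' @return One-row tibble: `mean_diff`, `ci_low`, `ci_high`, `n`.
#' @export
summarize_avg_benefit <- function(diffs, conf_level = 0.95) {
  if (length(diffs) < 2L) stop("need at least 2 predictions", call. = FALSE)
  if (anyNA(diffs)) stop("`diffs` must be complete", call. = FALSE)
  m <- mean(diffs)
  if (stats::sd(diffs) == 0) {
    warning("constant predicted differences: degenerate (zero-width) interval",
            call. = FALSE)
    return(tibble::tibble(mean_diff = m, ci_low = m, ci_high = m,
                          n = length(diffs)))
  }
  ci <- t_ci(diffs, conf_level)
  tibble::tibble(mean_diff = m, ci_low = ci[1], ci_high = ci[2], n = length(diffs))
}

#' Run the full three-step per-ethnicity validation
#'
#' Orchestrates the whole analysis from one configuration: builds the
#' outcome cohort (eligibility + outcome-window selection), then for every
#' analysis ethnicity group runs the closed testing procedure per drug
#' class (step 1), applies the chosen updates to each arm's predictions
#' and assesses decile-level calibration of the updated predicted
#' differences via covariate-adjusted arm contrasts (step 2), and
#' summarizes unadjusted response, weight change and discontinuation in
#' the five clinical-threshold subgroups (step 3). Per-group RMSE of
#' absolute predictions and mean predicted benefit with 95% CI are also
#' reported. The run is deterministic given the simulation seed.
#'
#' @param config A [run_config()].
#' @param outdir Optional directory; when given, the decision, calibration
#'   and subgroup tables are written as CSV plus a JSON manifest
#'   (`manifest.json`) recording the configuration fingerprint, seed and
#'   row counts.
#' @return A list of class `validation_report`: `decisions`,
#'   `calibration`, `subgroups`, `group_summary` (RMSE + average benefit
#'   per group), `attrition`, `cohort` (the built cohort with appended
#'   predictions) and `config`.
#' @export
run_validation <- function(config, outdir = NULL) {
  stopifnot(inherits(config, "run_config"))
  raw <- if (!is.null(config$sim)) simulate_cohort(config$sim)
         else read_cohort_csv(config$cohort_file)
  cohort <- build_cohort(raw, eligibility_rule(), target_month = config$target_month,
                         window = config$window)
  attrition <- attr(cohort, "attrition")
  spec <- config$model

  decisions <- recalibrate_cohort(cohort, spec, alpha = config$alpha,
                                  df_convention = config$df_convention,
                                  pool_mixed_other = config$pool_mixed_other,
                                  min_n = config$min_n)

  cohort$group <- ethnicity_group(cohort$ethnicity, config$pool_mixed_other)
  preds <- predicted_difference(spec, cohort)
  cohort$pred_sglt2i <- update_arm(preds$pred_sglt2i, cohort$group, "SGLT2i", decisions)
  cohort$pred_dpp4i <- update_arm(preds$pred_dpp4i, cohort$group, "DPP4i", decisions)
  cohort$pred_diff <- cohort$pred_sglt2i - cohort$pred_dpp4i
  cohort$pred_assigned <- ifelse(cohort$drug == "SGLT2i",
                                 cohort$pred_sglt2i, cohort$pred_dpp4i)

  groups <- intersect(ethnicity_groups(config$pool_mixed_other), unique(cohort$group))
  calib <- purrr::map_dfr(groups, function(g) {
    rows <- cohort[cohort$group == g, ]
    # each decile must hold comfortably more rows than adjustment parameters
    if (nrow(rows) < 300) {
      warning(sprintf("group %s has %d rows (< 300): decile calibration skipped",
                      g, nrow(rows)), call. = FALSE)
      return(NULL)
    }
    dplyr::mutate(calibration_table(rows, rows$pred_diff,
                                    adjust_imd = config$adjust_imd,
                                    spline_month = config$spline_month),
                  ethnicity = g, .before = 1)
  })
  subgroups <- purrr::map_dfr(groups, function(g) {
    rows <- cohort[cohort$group == g, ]
    dplyr::mutate(subgroup_summary(rows, rows$pred_diff), ethnicity = g, .before = 1)
  })
  group_summary <- purrr::map_dfr(groups, function(g) {
    rows <- cohort[cohort$group == g, ]
    bene <- summarize_avg_benefit(rows$pred_diff)
    tibble::tibble(ethnicity = g, n = nrow(rows),
                   rmse = rmse(rows$outcome_hba1c, rows$pred_assigned),
                   mean_pred_diff = bene$mean_diff,
                   ci_low = bene$ci_low, ci_high = bene$ci_high)
  })

  report <- structure(
    list(decisions = decisions, calibration = calib, subgroups = subgroups,
         group_summary = group_summary,
         attrition = tibble::tibble(rule = names(attrition),
                                    removed = as.integer(attrition)),
         cohort = cohort, config = config),
    class = "validation_report")
  if (!is.null(outdir)) write_report(report, outdir)
  report
}

update_arm <- function(pred, group, drug, decisions) {
  out <- pred
  dd <- decisions[decisions$drug == drug, ]
  for (i in seq_len(nrow(dd))) {
    idx <- group == dd$ethnicity[i]
    out[idx] <- dd$a[i] + dd$b[i] * pred[idx]
  }
  out
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report>\n")
  cat("  cohort rows:", nrow(x$cohort), "\n")
  cat("  closed-test decisions:\n")
  d <- x$decisions
  for (i in seq_len(nrow(d))) {
    cat(sprintf("    %-11s %-7s -> %s (a = %6.2f, b = %5.3f)\n",
                d$ethnicity[i], d$drug[i], d$chosen[i], d$a[i], d$b[i]))
  }
  cat("  per-group summary:\n")
  g <- x$group_summary
  for (i in seq_len(nrow(g))) {
    cat(sprintf("    %-11s n = %6d  RMSE = %5.2f  mean diff = %5.2f [%5.2f, %5.2f]\n",
                g$ethnicity[i], g$n[i], g$rmse[i], g$mean_pred_diff[i],
                g$ci_low[i], g$ci_high[i]))
  }
  invisible(x)
}

#' Write a validation report to disk
#'
#' Writes `decisions.csv`, `calibration.csv`, `subgroups.csv`,
#' `group_summary.csv`, `attrition.csv` and a `manifest.json` with the
#' configuration fingerprint, seed and row counts.
#'
#' @param report A `validation_report` from [run_validation()].
#' @param outdir Output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_report <- function(report, outdir) {
  stopifnot(inherits(report, "validation_report"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(report$decisions, file.path(outdir, "decisions.csv"))
  readr::write_csv(report$calibration, file.path(outdir, "calibration.csv"))
  readr::write_csv(report$subgroups, file.path(outdir, "subgroups.csv"))
  readr::write_csv(report$group_summary, file.path(outdir, "group_summary.csv"))
  readr::write_csv(report$attrition, file.path(outdir, "attrition.csv"))
  cfg <- report$config
  manifest <- list(
    seed = if (!is.null(cfg$sim)) cfg$sim$seed else NA_integer_,
    n_input = if (!is.null(cfg$sim)) cfg$sim$n else NA_integer_,
    n_cohort = nrow(report$cohort),
    alpha = cfg$alpha, df_convention = cfg$df_convention,
    target_month = cfg$target_month, pool_mixed_other = cfg$pool_mixed_other,
    adjust_imd = cfg$adjust_imd,
    config_hash = config_fingerprint(cfg),
    n_per_group = as.list(table(report$cohort$group))
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(outdir)
}

config_fingerprint <- function(cfg) {
  # stable digest-free fingerprint: deparse the config sans environments
  x <- utils::capture.output(utils::str(cfg, digits.d = 10, list.len = 1000))
  sprintf("%08x", sum(utf8ToInt(paste(x, collapse = "")) *
                        (seq_along(utf8ToInt(paste(x, collapse = ""))) %% 97 + 1)) %% .Machine$integer.max)
}
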