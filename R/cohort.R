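#' Eligibility rule for cohort construction
#'
#' Inclusion bounds applied to candidate drug initiations: baseline HbA1c
#' strictly above `hba1c_low` and strictly below `hba1c_high` (mmol/mol),
#' eGFR strictly above `egfr_min`, no insulin treatment, and -- for the
#' HbA1c-outcome cohort -- stable background therapy around initiation
#' (consumed as a pre-computed flag).
#'
#' @param hba1c_low,hba1c_high Exclusive baseline HbA1c bounds, mmol/mol.
#' @param egfr_min Exclusive eGFR lower bound, mL/min/1.73m2.
#' @param insulin_allowed Keep insulin-treated rows?
#' @param require_stable_therapy Require the stable-therapy flag?
#' @return A list of class `eligibility_rule`.
#' @export
eligibility_rule <- function(hba1c_low = 53, hba1c_high = 120, egfr_min = 45,
                             insulin_allowed = FALSE, require_stable_therapy = TRUE) {
  if (hba1c_low >= hba1c_high) stop("hba1c_low must be < hba1c_high", call. = FALSE)
  structure(list(hba1c_low = hba1c_low, hba1c_high = hba1c_high, egfr_min = egfr_min,
                 insulin_allowed = insulin_allowed,
                 require_stable_therapy = require_stable_therapy),
            class = "eligibility_rule")
}

#' Apply eligibility and complete-case filtering
#'
#' Keeps exactly the rows satisfying every bound strictly (HbA1c >
#' `hba1c_low` and < `hba1c_high`, eGFR > `egfr_min`, not insulin treated
#' unless allowed, stable therapy if required) and with complete data for
#' all five model predictors. Row order is preserved and the operation is
#' idempotent. A per-rule attrition count is attached as the `"attrition"`
#' attribute (rules applied sequentially, in the order listed).
#'
#' @param rows Cohort tibble (see [simulate_cohort()] for the columns).
#' @param rule An [eligibility_rule()].
#' @return The surviving rows, with an `"attrition"` attribute.
#' @export
apply_eligibility <- function(rows, rule = eligibility_rule()) {
  stopifnot(inherits(rule, "eligibility_rule"))
  rows <- tibble::as_tibble(rows)
  attrition <- integer(0)
  drop_step <- function(rows, keep, label) {
    keep[is.na(keep)] <- FALSE
    attrition[[label]] <<- sum(!keep)
    attrition <<- unlist(attrition)
    rows[keep, , drop = FALSE]
  }
  rows <- drop_step(rows, rows$baseline_hba1c > rule$hba1c_low, "hba1c_low")
  rows <- drop_step(rows, rows$baseline_hba1c < rule$hba1c_high, "hba1c_high")
  rows <- drop_step(rows, rows$egfr > rule$egfr_min, "egfr_min")
  if (!rule$insulin_allowed) {
    rows <- drop_step(rows, !rows$insulin_treated, "insulin")
  }
  if (rule$require_stable_therapy) {
    rows <- drop_step(rows, rows$stable_therapy, "stable_therapy")
  }
  complete <- !Reduce(`|`, lapply(rows[model_features], is.na))
  if (length(complete) == 0) complete <- logical(0)
  rows <- drop_step(rows, complete, "incomplete_predictors")
  attr(rows, "attrition") <- attrition
  rows
}

#' Resolve a patient's ethnicity from multiple recorded codes
#'
#' Picks the group with the highest number of recorded codes; if counts are
#' tied, the group of the most recent code among the tied groups. A residual
#' two-way tie (equal counts *and* equal latest dates) is broken
#' alphabetically on the group name, with a warning.
#'
#' @param records Data frame with columns `group` (an [ethnicity_levels()]
#'   value) and `date` (a `Date` or anything `as.Date()` accepts).
#' @return A single ethnicity level, or `NA_character_` (with a warning) if
#'   no records exist -- the missing-ethnicity signal, after which the row
#'   is excluded from ethnicity-stratified analyses.
#' @export
resolve_ethnicity <- function(records) {
  records <- tibble::as_tibble(records)
  if (nrow(records) == 0) {
    warning("no ethnicity records: returning NA", call. = FALSE)
    return(NA_character_)
  }
  stopifnot(all(c("group", "date") %in% names(records)))
  bad <- setdiff(unique(records$group), ethnicity_levels())
  if (length(bad) > 0) stop("unknown ethnicity groups: ", paste(bad, collapse = ", "),
                            call. = FALSE)
  records$date <- as.Date(records$date)
  counts <- table(records$group)
  top <- names(counts)[counts == max(counts)]
  if (length(top) == 1L) return(top)
  tied <- records[records$group %in% top, ]
  latest <- tied[tied$date == max(tied$date), ]
  winners <- sort(unique(latest$group))
  if (length(winners) > 1L) {
    warning("ethnicity tie on both count and latest date; using alphabetical order",
            call. = FALSE)
  }
  winners[1L]
}

#' Select the outcome HbA1c record closest to the target month
#'
#' Among records with month inside the (inclusive) window, returns the one
#' minimizing `|month - target_month|`; when two records are equidistant the
#' earlier month wins (favouring an on-treatment measurement). Returns a
#' zero-row tibble when no record falls in the window.
#'
#' @param records Data frame with numeric columns `month` (> 0) and `value`.
#' @param target_month Target month (6 for the primary outcome, 12 for the
#'   longer-term sensitivity outcome).
#' @param window Inclusive month window, default `c(3, 15)`.
#' @return One-row tibble with `month` and `value`, or a zero-row tibble.
#' @export
select_outcome_record <- function(records, target_month = 6, window = c(3, 15)) {
  records <- tibble::as_tibble(records)
  stopifnot(all(c("month", "value") %in% names(records)))
  if (any(records$month <= 0)) stop("record months must be positive", call. = FALSE)
  ok <- records[records$month >= window[1] & records$month <= window[2], ]
  if (nrow(ok) == 0) return(ok[0, c("month", "value")])
  ord <- order(abs(ok$month - target_month), ok$month)
  ok[ord[1L], c("month", "value")]
}

#' Parse / format the serialized HbA1c record list
#'
#' The cohort CSV dialect stores each row's HbA1c records in one column as a
#' semicolon-delimited `month:value` list. `parse_hba1c_records()` turns the
#' character vector into a list of tibbles; `format_hba1c_records()` is its
#' inverse.
#'
#' @param x Character vector of serialized record lists.
#' @return A list of tibbles with columns `month`, `value`.
#' @export
parse_hba1c_records <- function(x) {
  lapply(strsplit(as.character(x), ";", fixed = TRUE), function(parts) {
    mv <- strsplit(parts, ":", fixed = TRUE)
    tibble::tibble(month = as.numeric(vapply(mv, `[`, "", 1L)),
                   value = as.numeric(vapply(mv, `[`, "", 2L)))
  })
}

#' @rdname parse_hba1c_records
#' @param records List of data frames with columns `month`, `value`.
#' @export
format_hba1c_records <- function(records) {
  vapply(records, function(r) {
    paste(sprintf("%.8g:%.10g", r$month, r$value), collapse = ";")
  }, "")
}

# Vectorized window selection over the serialized records column.
# Long-format trick: explode all records, filter the window, order by
# (row, |month - target|, month) and keep the first record per row.
select_outcomes_vectorized <- function(rec_strings, target_month, window) {
  recs <- strsplit(as.character(rec_strings), ";", fixed = TRUE)
  lens <- lengths(recs)
  row_id <- rep(seq_along(recs), lens)
  flat <- unlist(recs, use.names = FALSE)
  colon <- regexpr(":", flat, fixed = TRUE)
  month <- as.numeric(substr(flat, 1L, colon - 1L))
  value <- as.numeric(substring(flat, colon + 1L))
  keep <- month >= window[1] & month <= window[2]
  row_id <- row_id[keep]; month <- month[keep]; value <- value[keep]
  ord <- order(row_id, abs(month - target_month), month)
  first <- ord[!duplicated(row_id[ord])]
  out_month <- rep(NA_real_, length(recs))
  out_value <- rep(NA_real_, length(recs))
  out_month[row_id[first]] <- month[first]
  out_value[row_id[first]] <- value[first]
  tibble::tibble(outcome_month = out_month, outcome_hba1c = out_value)
}

#' Build the analysis cohort: eligibility, then outcome-window selection
#'
#' Applies [apply_eligibility()], then derives `outcome_hba1c` /
#' `outcome_month` by selecting, for each row, the HbA1c record closest to
#' `target_month` inside the window (see [select_outcome_record()]); rows
#' with no in-window record are dropped. The combined per-rule attrition log
#' is attached as the `"attrition"` attribute.
#'
#' Because the window itself does not move, changing `target_month` (6
#' versus 12 for the sensitivity analysis) changes only which in-window
#' record is selected, never cohort membership.
#'
#' @param rows Cohort tibble with an `hba1c_records` column (serialized, see
#'   [parse_hba1c_records()]) or `outcome-`ready `month`/`value` list column.
#' @param rule An [eligibility_rule()].
#' @param target_month Target outcome month.
#' @param window Inclusive outcome window in months.
#' @return Eligible rows with `outcome_hba1c` and `outcome_month` appended.
#' @export
build_cohort <- function(rows, rule = eligibility_rule(), target_month = 6,
                         window = c(3, 15)) {
  if (target_month < window[1] || target_month > window[2]) {
    stop("`target_month` must lie inside the outcome window", call. = FALSE)
  }
  rows <- apply_eligibility(rows, rule)
  attrition <- attr(rows, "attrition")
  if (nrow(rows) == 0) {
    rows$outcome_month <- double(0)
    rows$outcome_hba1c <- double(0)
    attr(rows, "attrition") <- c(attrition, no_outcome_record = 0L)
    return(rows)
  }
  sel <- select_outcomes_vectorized(rows$hba1c_records, target_month, window)
  rows$outcome_month <- sel$outcome_month
  rows$outcome_hba1c <- sel$outcome_hba1c
  keep <- !is.na(rows$outcome_hba1c)
  attrition <- c(attrition, no_outcome_record = sum(!keep))
  rows <- rows[keep, , drop = FALSE]
  attr(rows, "attrition") <- attrition
  rows
}

#' Read / write the cohort CSV dialect
#'
#' Headered CSV with one row per drug initiation and the `hba1c_records`
#' column serialized as a semicolon-delimited `month:value` list.
#'
#' @param path CSV file path.
#' @return `read_cohort_csv()` returns a tibble; `write_cohort_csv()`
#'   returns `path` invisibly.
#' @export
read_cohort_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    patient_id = readr::col_character(),
                    drug = readr::col_character(),
                    ethnicity = readr::col_character(),
                    sex = readr::col_character(),
                    hba1c_records = readr::col_character(),
                    .default = readr::col_guess()))
}

#' @rdname read_cohort_csv
#' @param rows Cohort tibble.
#' @export
write_cohort_csv <- function(rows, path) {
  readr::write_csv(tibble::as_tibble(rows), path)
  invisible(path)
}
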