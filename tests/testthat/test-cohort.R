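test_that("eligibility bounds are strict and rows violating one rule drop", {
  base <- toy_cohort_rows(6)
  base$baseline_hba1c <- c(53, 70, 70, 70, 70, 70)   # row 1: at the low bound
  base$egfr <- c(90, 90, 45, 90, 90, 90)             # row 3: at the eGFR bound
  base$baseline_hba1c[2] <- 120                      # row 2: at the high bound
  base$insulin_treated[4] <- TRUE
  base$stable_therapy[5] <- FALSE                    # row 6 is fully compliant
  kept <- apply_eligibility(base)
  expect_equal(kept$patient_id, base$patient_id[6])
  att <- attr(kept, "attrition")
  expect_equal(unname(att[c("hba1c_low", "hba1c_high", "egfr_min",
                            "insulin", "stable_therapy")]),
               c(1L, 1L, 1L, 1L, 1L))
})

test_that("eligibility filtering is idempotent, order-preserving and total", {
  expect_equal(nrow(apply_eligibility(toy_cohort_rows(0))), 0L)
  set.seed(201)
  for (rep in 1:5) {
    rows <- toy_cohort_rows(40, seed = 300 + rep)
    rows$baseline_hba1c <- runif(40, 40, 130)
    rows$egfr <- runif(40, 30, 140)
    rows$insulin_treated <- runif(40) < 0.2
    rows$stable_therapy <- runif(40) < 0.8
    rows$log_alt[sample(40, 3)] <- NA
    once <- apply_eligibility(rows)
    twice <- apply_eligibility(once)
    expect_equal(nrow(twice), nrow(once))
    strip <- function(x) { attr(x, "attrition") <- NULL; as.data.frame(x) }
    expect_equal(strip(once), strip(twice))
    expect_true(all(once$baseline_hba1c > 53 & once$baseline_hba1c < 120))
    expect_true(all(once$egfr > 45))
    expect_true(all(!once$insulin_treated & once$stable_therapy))
    expect_true(all(!is.na(once$log_alt)))
    expect_true(!is.unsorted(match(once$patient_id, rows$patient_id)))
  }
})

test_that("ethnicity resolves by plurality, then most recent code", {
  rec <- function(groups, dates) data.frame(group = groups, date = as.Date(dates))
  expect_equal(resolve_ethnicity(rec(c("White", "White", "Black"),
                                     c("2019-01-01", "2020-01-01", "2022-01-01"))),
               "White")
  expect_equal(resolve_ethnicity(rec(c("White", "Black"),
                                     c("2019-05-01", "2022-03-01"))),
               "Black")
  expect_equal(resolve_ethnicity(rec("SouthAsian", "2020-06-01")), "SouthAsian")
  # permutation invariance
  r <- rec(c("Mixed", "White", "White", "Mixed", "Black"),
           c("2018-01-01", "2019-01-01", "2020-01-01", "2021-01-01", "2017-01-01"))
  for (i in 1:4) {
    expect_equal(resolve_ethnicity(r[sample(nrow(r)), ]), resolve_ethnicity(r))
  }
  # full tie (count and latest date): alphabetical with a warning
  expect_warning(
    out <- resolve_ethnicity(rec(c("White", "Black"), c("2020-01-01", "2020-01-01"))),
    "tie")
  expect_equal(out, "Black")
  expect_warning(expect_true(is.na(resolve_ethnicity(rec(character(), as.Date(character()))))),
                 "no ethnicity records")
})

test_that("outcome record selection honours window, distance and tie-break", {
  rec <- function(m, v = seq_along(m)) data.frame(month = m, value = v)
  expect_equal(select_outcome_record(rec(c(5, 8)))$month, 5)
  expect_equal(nrow(select_outcome_record(rec(c(2, 16)))), 0L)
  expect_equal(select_outcome_record(rec(6))$month, 6)
  # equidistant records: the earlier month wins
  expect_equal(select_outcome_record(rec(c(7, 5)))$month, 5)
  # inclusive window endpoints
  expect_equal(select_outcome_record(rec(c(3, 15)))$month, 3)
  # 12-month sensitivity target re-ranks the same records
  expect_equal(select_outcome_record(rec(c(5, 14)), target_month = 12)$month, 14)
  expect_error(select_outcome_record(rec(c(-1, 6))), "positive")
})

test_that("record serialization round-trips", {
  recs <- list(data.frame(month = c(5.25, 11), value = c(63.2, 58.91)),
               data.frame(month = 6, value = 70.5))
  parsed <- parse_hba1c_records(format_hba1c_records(recs))
  expect_equal(parsed[[1]]$month, recs[[1]]$month)
  expect_equal(parsed[[1]]$value, recs[[1]]$value)
  expect_equal(parsed[[2]]$value, recs[[2]]$value)
})

test_that("build_cohort derives the outcome and logs attrition", {
  rows <- toy_cohort_rows(5)
  rows$hba1c_records <- c("5:60;8:70", "2:50;16:55", "6:64", "7:66;5:62", "4:58;3:57")
  out <- build_cohort(rows)
  expect_equal(nrow(out), 4L)  # the all-out-of-window row drops
  expect_equal(out$outcome_hba1c, c(60, 64, 62, 58))
  expect_equal(out$outcome_month, c(5, 6, 5, 4))
  att <- attr(out, "attrition")
  expect_equal(unname(att[["no_outcome_record"]]), 1L)
  # vectorized path agrees with the scalar selector
  recs <- parse_hba1c_records(rows$hba1c_records)
  scalar <- lapply(recs, select_outcome_record)
  kept <- which(vapply(scalar, nrow, 0L) == 1L)
  expect_equal(out$outcome_month, vapply(scalar[kept], function(r) r$month, 0))

  expect_error(build_cohort(rows, target_month = 20), "window")
})

test_that("target month 12 changes only the selected record, not membership", {
  sc <- sim_config(n = 1500, seed = 63)
  raw <- simulate_cohort(sc)
  m6 <- build_cohort(raw, target_month = 6)
  m12 <- build_cohort(raw, target_month = 12)
  expect_identical(m6$patient_id, m12$patient_id)
  expect_true(any(m6$outcome_month != m12$outcome_month))
})

test_that("cohort CSV round-trips through the documented dialect", {
  path <- withr::local_tempfile(fileext = ".csv")
  co <- simulate_cohort(sim_config(n = 50, seed = 4))
  write_cohort_csv(co, path)
  back <- read_cohort_csv(path)
  expect_equal(as.data.frame(back[names(co)]), as.data.frame(co), tolerance = 1e-9)
  # and the built cohorts agree
  expect_equal(build_cohort(back)$outcome_hba1c, build_cohort(co)$outcome_hba1c,
               tolerance = 1e-9)
})
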