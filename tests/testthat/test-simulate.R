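test_that("same config and seed give byte-identical cohorts", {
  sc <- sim_config(n = 500, seed = 123)
  a <- simulate_cohort(sc)
  b <- simulate_cohort(sc)
  expect_identical(a, b)
  # and a different seed gives a different cohort
  c2 <- simulate_cohort(sim_config(n = 500, seed = 124))
  expect_false(identical(a$baseline_hba1c, c2$baseline_hba1c))
})

test_that("config validation rejects bad inputs", {
  expect_error(sim_config(n = -1), "non-negative")
  expect_error(sim_config(ethnicity_props = c(White = 0.8, SouthAsian = 0.3,
                                              Black = 0.046, MixedOther = 0.025)),
               "sum to 1")
  expect_error(sim_config(noise_sd = -2), ">= 0")
  expect_equal(nrow(simulate_cohort(sim_config(n = 0))), 0L)
})

test_that("ethnicity mix matches the configured proportions at n = 20000", {
  co <- simulate_cohort(sim_config(n = 20000, seed = 5))
  frac <- prop.table(table(ethnicity_group(co$ethnicity))) * 100
  expect_lt(abs(frac[["White"]] - 78.5), 1)
  expect_lt(abs(frac[["Black"]] - 4.6), 1)
  expect_lt(abs(frac[["SouthAsian"]] - 14.4), 1)
  expect_lt(abs(frac[["MixedOther"]] - 2.5), 1)
})

test_that("covariate means converge to the truncated-normal expectation", {
  n <- 20000
  co <- simulate_cohort(sim_config(n = n, seed = 8))
  cp <- default_covariate_params()
  trunc_mean <- function(mu, sigma, lo, hi) {
    # closed form for the mean of a truncated normal
    a <- (lo - mu) / sigma
    b <- (hi - mu) / sigma
    mu + sigma * (dnorm(a) - dnorm(b)) / (pnorm(b) - pnorm(a))
  }
  for (i in seq_len(nrow(cp))) {
    target <- trunc_mean(cp$mean[i], cp$sd[i], cp$lower[i], cp$upper[i])
    expect_lt(abs(mean(co[[cp$feature[i]]]) - target), 3 * cp$sd[i] / sqrt(n))
    # and the truncation itself moves the mean by < 2.5 units on each scale
    expect_lt(abs(target - cp$mean[i]), 2.5)
  }
})

test_that("zero noise and zero shifts reproduce the truth model exactly", {
  sc <- sim_config(n = 300, seed = 42, noise_sd = 0, shift = zero_shift_map())
  co <- build_cohort(simulate_cohort(sc))
  pred <- predict_outcome(sc$truth_model, co, co$drug)
  expect_equal(co$outcome_hba1c, pred, tolerance = 1e-6)
  expect_equal(co$outcome_hba1c, co$true_outcome, tolerance = 1e-6)
})

test_that("propensity coefficients control confounding", {
  sc <- sim_config(n = 8000, seed = 31)
  co <- simulate_cohort(sc)
  m <- tapply(co$baseline_hba1c, co$drug, mean)
  expect_gt(m[["SGLT2i"]], m[["DPP4i"]])  # SGLT2i users have higher baseline HbA1c
  a <- tapply(co$age, co$drug, mean)
  expect_lt(a[["SGLT2i"]], a[["DPP4i"]])  # and are younger

  pc0 <- c(intercept = 0, baseline_hba1c = 0, age = 0, bmi = 0, egfr = 0)
  co0 <- simulate_cohort(sim_config(n = 8000, seed = 31, propensity_coefs = pc0))
  m0 <- tapply(co0$baseline_hba1c, co0$drug, mean)
  # randomized arms are exchangeable: difference within 3 pooled SEs
  se <- sqrt(sum(tapply(co0$baseline_hba1c, co0$drug, var) /
                   table(co0$drug)))
  expect_lt(abs(m0[["SGLT2i"]] - m0[["DPP4i"]]), 3 * se)
})

test_that("planted intercept shifts are recovered as mean residuals", {
  sc <- single_cell_config(6000, seed = 77, group = "SouthAsian", drug = "DPP4i",
                           shift_value = -4)
  co <- build_cohort(simulate_cohort(sc))
  pred <- predict_outcome(sc$truth_model, co, "DPP4i")
  mc_se <- 12 / sqrt(nrow(co))
  expect_lt(abs(mean(co$outcome_hba1c - pred) - (-4)), 3 * mc_se)
})

test_that("true_difference returns the noise-free planted contrast", {
  rows <- toy_cohort_rows(8)

  # zero drug terms, zero shifts -> 0 everywhere
  flat <- sim_config(n = 8, truth_model = model_spec(intercept = 50),
                     shift = zero_shift_map())
  expect_equal(true_difference(flat, rows), rep(0, 8))

  # drug main effect only -> constant
  dm <- sim_config(n = 8, truth_model = model_spec(intercept = 50, drug_main = -5),
                   shift = zero_shift_map())
  expect_equal(true_difference(dm, rows), rep(-5, 8))

  # drug x BMI interaction: hand-computed linear-predictor difference
  sc <- sim_config(n = 8, truth_model = toy_spec(), shift = zero_shift_map())
  expect_equal(true_difference(sc, rows), 1 + 0.1 * rows$bmi)

  # shifts enter with the ethnicity-group sign structure
  sc2 <- sim_config(n = 8, truth_model = toy_spec())  # default shift map
  grp <- ethnicity_group(rows$ethnicity)
  sm <- default_shift_map()
  key <- paste(sm$ethnicity_group, sm$drug)
  delta <- sm$shift[match(paste(grp, "SGLT2i"), key)] -
    sm$shift[match(paste(grp, "DPP4i"), key)]
  expect_equal(true_difference(sc2, rows), 1 + 0.1 * rows$bmi + delta)
})

test_that("decoy records never displace the primary outcome record", {
  sc <- sim_config(n = 2000, seed = 55, noise_sd = 0, shift = zero_shift_map())
  co <- build_cohort(simulate_cohort(sc))
  # with zero noise the selected record must be the primary one everywhere,
  # so outcome equals the truth prediction even though decoys exist
  expect_equal(co$outcome_hba1c, co$true_outcome, tolerance = 1e-6)
  recs <- parse_hba1c_records(co$hba1c_records)
  expect_true(any(lengths(lapply(recs, function(r) r$month)) > 1))
  expect_true(all(vapply(recs, function(r) all(r$month > 0), logical(1))))
})

test_that("planted ineligible rows violate exactly the intended rules", {
  sc <- sim_config(n = 1000, seed = 9, ineligible_frac = 0.02)
  co <- simulate_cohort(sc)
  expect_equal(sum(co$baseline_hba1c <= 53), 20)
  expect_equal(sum(co$baseline_hba1c >= 120), 20)
  expect_equal(sum(co$egfr <= 45), 20)
  expect_equal(sum(co$insulin_treated), 20)
  expect_equal(sum(!co$stable_therapy), 20)
  kept <- apply_eligibility(co)
  expect_equal(nrow(kept), 1000 - 100)
})

test_that("secondary outcomes follow their per-drug configuration", {
  co <- simulate_cohort(sim_config(n = 12000, seed = 14))
  w <- tapply(co$weight_change, co$drug, mean)
  expect_lt(w[["SGLT2i"]], w[["DPP4i"]])  # greater weight loss on SGLT2i
  expect_true(all(co$discontinued %in% c(TRUE, FALSE)))
  # benefit-dependent discontinuation: SGLT2i initiators with DPP4i-favoured
  # true benefit discontinue more often
  s <- co[co$drug == "SGLT2i", ]
  expect_gt(mean(s$discontinued[s$true_diff > 0]),
            mean(s$discontinued[s$true_diff < -3]))
})
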