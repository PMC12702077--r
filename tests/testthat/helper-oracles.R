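# Independent oracles and small fixtures shared across the suite.

# Brute-force restricted truncated-power cubic for 3 knots, written from the
# closed form (not via rcs_basis) so the two paths are independent.
oracle_rcs_nonlinear <- function(x, k) {
  tp <- function(u) ifelse(u > 0, u^3, 0)
  (tp(x - k[1]) -
     tp(x - k[2]) * (k[3] - k[1]) / (k[3] - k[2]) +
     tp(x - k[3]) * (k[2] - k[1]) / (k[3] - k[2])) / (k[3] - k[1])^2
}

# Normal-equations least squares: coefficients via solve(X'X, X'y).
oracle_ols <- function(X, y) {
  drop(solve(crossprod(X), crossprod(X, y)))
}

# A tiny hand-checkable model: intercept 2, HbA1c slope 0.5, BMI slope -0.2,
# drug main effect 1, drug x BMI interaction 0.1.
toy_spec <- function() {
  model_spec(
    intercept = 2,
    terms = data.frame(feature = c("baseline_hba1c", "bmi"),
                       basis = c(1L, 1L), coef = c(0.5, -0.2)),
    drug_main = 1,
    drug_interactions = data.frame(feature = "bmi", basis = 1L, coef = 0.1)
  )
}

# Minimal complete covariate rows for prediction tests.
toy_rows <- function(n = 4, seed = 42) {
  set.seed(seed)
  tibble::tibble(
    baseline_hba1c = runif(n, 55, 110), age = runif(n, 30, 85),
    bmi = runif(n, 20, 45), egfr = runif(n, 50, 130),
    log_alt = runif(n, 2, 4.5)
  )
}

# Fully populated cohort-shaped rows with hand-settable outcomes, for the
# builder / calibration / subgroup tests.
toy_cohort_rows <- function(n = 12, seed = 99) {
  set.seed(seed)
  dplyr::mutate(
    toy_rows(n, seed = seed),
    patient_id = sprintf("T%03d", seq_len(n)),
    drug = rep(c("SGLT2i", "DPP4i"), length.out = n),
    ethnicity = sample(ethnicity_levels(), n, replace = TRUE),
    sex = rep(c("F", "M"), length.out = n),
    imd_quintile = sample(1:5, n, replace = TRUE),
    n_current_drugs = sample(0:3, n, replace = TRUE),
    n_ever_classes = sample(2:4, n, replace = TRUE),
    insulin_treated = FALSE, stable_therapy = TRUE,
    hba1c_records = sprintf("6:%g", round(runif(n, 50, 90), 2)),
    weight_change = rnorm(n), discontinued = runif(n) < 0.2,
    outcome_month = 6, outcome_hba1c = as.numeric(sub("^6:", "", hba1c_records))
  )
}

# Single-cell simulation config: one ethnicity group, one drug arm.
single_cell_config <- function(n, seed, group = "White", drug = "DPP4i",
                               shift_value = 0, noise_sd = 12) {
  props <- c(White = 0, SouthAsian = 0, Black = 0, MixedOther = 0)
  props[group] <- 1
  sm <- zero_shift_map()
  sm$shift[sm$ethnicity_group == group & sm$drug == drug] <- shift_value
  pc <- c(intercept = if (drug == "SGLT2i") 50 else -50,
          baseline_hba1c = 0, age = 0, bmi = 0, egfr = 0)
  sim_config(n = n, seed = seed, ethnicity_props = props,
             propensity_coefs = pc, shift = sm, noise_sd = noise_sd)
}
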