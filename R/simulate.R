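#' Default covariate distribution parameters
#'
#' Per-feature mean, SD and truncation bounds for the five clinical features,
#' on their natural scales (HbA1c mmol/mol, age years, BMI kg/m2, eGFR
#' mL/min/1.73m2, ALT on the log-IU/L scale). Means and SDs sit between the
#' two arms of a typical UK primary-care second-line cohort; truncation
#' bounds are strictly inside the eligibility bounds (HbA1c >53 and <120,
#' eGFR >45) so that eligibility violations occur only through rows planted
#' via `ineligible_frac`, never through the tails of the covariate draws.
#'
#' @return A tibble with columns `feature`, `mean`, `sd`, `lower`, `upper`.
#' @export
default_covariate_params <- function() {
  tibble::tribble(
    ~feature,         ~mean, ~sd,  ~lower, ~upper,
    "baseline_hba1c", 73.5,  14,   54,     119.5,
    "age",            61,    11.5, 18,     95,
    "bmi",            32.5,  6.5,  16,     60,
    "egfr",           91,    17,   45.5,   140,
    "log_alt",        3.3,   0.5,  1.5,    5.5
  )
}

#' Default treatment-assignment (propensity) coefficients
#'
#' Logistic-regression coefficients on the raw covariate scales mapping a
#' row to its probability of initiating SGLT2i rather than DPP4i. The signs
#' emulate confounding by indication as seen in routine data: SGLT2i
#' initiators are younger with higher baseline HbA1c, BMI and eGFR. The
#' intercept is set so that roughly 37% of initiations are SGLT2i at the
#' default covariate means. Setting every coefficient (and the intercept) to
#' zero yields randomized 50/50 arms.
#'
#' @return Named numeric vector with elements `intercept`, `baseline_hba1c`,
#'   `age`, `bmi`, `egfr`.
#' @export
default_propensity_coefs <- function() {
  c(intercept = -2.28, baseline_hba1c = 0.014, age = -0.035, bmi = 0.046, egfr = 0.015)
}

#' Default per-(ethnicity group, drug) intercept shifts
#'
#' Additive shifts (mmol/mol) applied to the truth-model prediction when
#' generating outcomes, keyed by analysis ethnicity group and drug. The
#' defaults emulate the miscalibration pattern this validation framework is
#' designed to detect: observed DPP4i responses 1.6-3 mmol/mol greater
#' (i.e. lower achieved HbA1c) than predicted, most pronounced in non-White
#' groups, with SGLT2i predictions accurate in non-White groups and only a
#' small shift for White SGLT2i initiators.
#'
#' @return A tibble with columns `ethnicity_group`, `drug`, `shift`.
#' @export
default_shift_map <- function() {
  tibble::tribble(
    ~ethnicity_group, ~drug,    ~shift,
    "White",          "DPP4i",  -1.6,
    "SouthAsian",     "DPP4i",  -2.6,
    "Black",          "DPP4i",  -3.0,
    "MixedOther",     "DPP4i",  -2.6,
    "White",          "SGLT2i", -0.9,
    "SouthAsian",     "SGLT2i",  0,
    "Black",          "SGLT2i",  0,
    "MixedOther",     "SGLT2i",  0
  )
}

#' Build a zero shift map
#'
#' Convenience for null scenarios: every (ethnicity group, drug) shift is 0,
#' so outcomes are generated exactly from the truth model.
#'
#' @return A tibble with columns `ethnicity_group`, `drug`, `shift`, all
#'   shifts zero.
#' @export
zero_shift_map <- function() {
  dplyr::mutate(default_shift_map(), shift = 0)
}

#' Simulation configuration for the synthetic observational cohort
#'
#' Bundles and validates every knob of the generator. Defaults are the
#' reference study conditions used throughout the package's tests: ethnicity
#' mix 78.5 / 14.4 / 4.6 / 2.5% (White / South Asian / Black / Mixed+Other,
#' with the pooled share split evenly between Mixed and Other), covariate
#' distributions per [default_covariate_params()], confounded treatment
#' assignment per [default_propensity_coefs()], outcomes generated from
#' `truth_model` plus the per-(ethnicity group, drug) `shift` plus Gaussian
#' noise with SD 12 mmol/mol, and the primary outcome record at a month
#' drawn from Normal(6.7, 2.8) clipped to the 3-15 month window.
#'
#' @param n Number of drug initiations (rows).
#' @param seed Integer seed; all of the generator's randomness flows from it.
#' @param ethnicity_props Named numeric vector of four proportions summing
#'   to one, names `White`, `SouthAsian`, `Black`, `MixedOther`.
#' @param covariate_params Tibble as [default_covariate_params()].
#' @param propensity_coefs Named vector as [default_propensity_coefs()].
#' @param truth_model [model_spec()] generating the noise-free outcomes.
#' @param shift Tibble as [default_shift_map()].
#' @param noise_sd Outcome noise SD, mmol/mol (>= 0).
#' @param outcome_month_params Named vector `c(mean =, sd =)` for the month
#'   of the primary outcome record, clipped to the outcome window.
#' @param weight_params Tibble with columns `drug`, `mean`, `sd`: 6-month
#'   weight change, kg (SGLT2i more negative by default).
#' @param discontinuation_params Tibble with columns `drug`, `intercept`,
#'   `benefit_coef`: per-drug logit of 6-month discontinuation, with a slope
#'   on the row's true predicted difference so that SGLT2i discontinuation
#'   rises in DPP4i-favoured patients.
#' @param ineligible_frac Fraction of rows planted to violate each of the
#'   five eligibility rules (low HbA1c, high HbA1c, low eGFR, insulin
#'   treated, unstable therapy); each planted row violates exactly one rule.
#' @param outcome_window Inclusive month window of usable outcome records.
#'
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n = 10000,
                       seed = 1,
                       ethnicity_props = c(White = 0.785, SouthAsian = 0.144,
                                           Black = 0.046, MixedOther = 0.025),
                       covariate_params = default_covariate_params(),
                       propensity_coefs = default_propensity_coefs(),
                       truth_model = default_model_spec(),
                       shift = default_shift_map(),
                       noise_sd = 12,
                       outcome_month_params = c(mean = 6.7, sd = 2.8),
                       weight_params = tibble::tibble(
                         drug = c("SGLT2i", "DPP4i"),
                         mean = c(-2.5, -0.3), sd = c(4, 4)),
                       discontinuation_params = tibble::tibble(
                         drug = c("SGLT2i", "DPP4i"),
                         intercept = c(-1.9, -2.2),
                         benefit_coef = c(0.15, 0)),
                       ineligible_frac = 0,
                       outcome_window = c(3, 15)) {
  if (!is.numeric(n) || length(n) != 1L || n < 0 || n != floor(n)) {
    stop("`n` must be a non-negative integer", call. = FALSE)
  }
  if (abs(sum(ethnicity_props) - 1) > 1e-9) {
    stop("`ethnicity_props` must sum to 1 (got ", sum(ethnicity_props), ")", call. = FALSE)
  }
  if (any(ethnicity_props < 0)) stop("`ethnicity_props` must be non-negative", call. = FALSE)
  if (!setequal(names(ethnicity_props), ethnicity_groups(TRUE))) {
    stop("`ethnicity_props` must be named ", paste(ethnicity_groups(TRUE), collapse = ", "),
         call. = FALSE)
  }
  if (!is.numeric(noise_sd) || noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  if (ineligible_frac < 0 || ineligible_frac > 0.2) {
    stop("`ineligible_frac` must be in [0, 0.2]", call. = FALSE)
  }
  stopifnot(inherits(truth_model, "model_spec"))
  covariate_params <- tibble::as_tibble(covariate_params)
  stopifnot(all(c("feature", "mean", "sd", "lower", "upper") %in% names(covariate_params)),
            setequal(covariate_params$feature, model_features),
            all(covariate_params$lower < covariate_params$upper))
  shift <- tibble::as_tibble(shift)
  stopifnot(all(c("ethnicity_group", "drug", "shift") %in% names(shift)))
  structure(
    list(n = as.integer(n), seed = as.integer(seed),
         ethnicity_props = ethnicity_props[ethnicity_groups(TRUE)],
         covariate_params = covariate_params,
         propensity_coefs = propensity_coefs,
         truth_model = truth_model, shift = shift, noise_sd = noise_sd,
         outcome_month_params = outcome_month_params,
         weight_params = tibble::as_tibble(weight_params),
         discontinuation_params = tibble::as_tibble(discontinuation_params),
         ineligible_frac = ineligible_frac,
         outcome_window = as.numeric(outcome_window)),
    class = "sim_config"
  )
}

rtrunc_norm <- function(n, mean, sd, lower, upper) {
  out <- rnorm(n, mean, sd)
  for (iter in 1:100) {
    bad <- which(out < lower | out > upper)
    if (length(bad) == 0) return(out)
    out[bad] <- rnorm(length(bad), mean, sd)
  }
  # bounds many SDs out would starve rejection sampling; clamp the stragglers
  pmin(pmax(out, lower), upper)
}

lookup_shift <- function(shift, group, drug) {
  key <- paste(shift$ethnicity_group, shift$drug)
  idx <- match(paste(group, drug), key)
  if (anyNA(idx)) {
    stop("shift map lacks entries for: ",
         paste(unique(paste(group, drug)[is.na(idx)]), collapse = "; "), call. = FALSE)
  }
  shift$shift[idx]
}

#' Simulate an observational two-arm cohort with planted ground truth
#'
#' Generates one row per drug initiation. Covariates are truncated-normal
#' draws; the drug is assigned by the configured propensity model
#' (confounding by indication); the HbA1c record nearest the 6-month target
#' inside the outcome window equals the truth-model prediction for the
#' assigned drug, plus the configured (ethnicity group, drug) intercept
#' shift, plus Gaussian noise. Up to two decoy HbA1c records are added per
#' row -- one inside the window but strictly farther from the target month
#' than the primary record, one outside the window -- solely to exercise
#' outcome-window selection downstream. Secondary outcomes (6-month weight
#' change; discontinuation, whose logit depends on the row's true predicted
#' benefit) are drawn per configuration.
#'
#' All randomness flows from `config$seed` through one generator stream, in
#' this order: ethnicity, the five covariates (HbA1c, age, BMI, eGFR,
#' log-ALT), sex, IMD quintile, drug-history counts, treatment assignment,
#' outcome month, outcome noise, decoy structure, weight change,
#' discontinuation, planted-ineligibility row selection. Ground-truth
#' columns are prefixed `true_` and are not part of the observed-data
#' contract.
#'
#' @param config A [sim_config()].
#' @return A tibble with one row per initiation: identifiers, covariates,
#'   `drug`, `ethnicity`, flags, `hba1c_records` (semicolon-delimited
#'   `month:value` list), `weight_change`, `discontinued`, and ground-truth
#'   columns `true_outcome` (noise-free shifted prediction at the primary
#'   record) and `true_diff` (noise-free predicted SGLT2i - DPP4i
#'   difference including shifts).
#' @seealso [build_cohort()] to derive `outcome_hba1c` / `outcome_month`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n
  set.seed(config$seed)
  if (n == 0L) return(empty_cohort())

  props4 <- config$ethnicity_props
  # Mixed and Other split the pooled share evenly
  props5 <- c(White = unname(props4["White"]), SouthAsian = unname(props4["SouthAsian"]),
              Black = unname(props4["Black"]),
              Mixed = unname(props4["MixedOther"]) / 2,
              Other = unname(props4["MixedOther"]) / 2)
  ethnicity <- sample(names(props5), n, replace = TRUE, prob = props5)

  cp <- config$covariate_params
  cov <- list()
  for (f in model_features) {
    p <- cp[cp$feature == f, ]
    cov[[f]] <- rtrunc_norm(n, p$mean, p$sd, p$lower, p$upper)
  }

  sex <- sample(c("F", "M"), n, replace = TRUE, prob = c(0.38, 0.62))
  imd <- sample(1:5, n, replace = TRUE, prob = c(0.17, 0.18, 0.19, 0.22, 0.24))
  imd[runif(n) < 0.0005] <- NA_integer_
  n_current_drugs <- sample(0:3, n, replace = TRUE, prob = c(0.05, 0.52, 0.38, 0.05))
  n_ever_classes <- sample(2:4, n, replace = TRUE, prob = c(0.38, 0.38, 0.24))

  pc <- config$propensity_coefs
  lp <- pc[["intercept"]] +
    pc[["baseline_hba1c"]] * cov$baseline_hba1c +
    pc[["age"]] * cov$age + pc[["bmi"]] * cov$bmi + pc[["egfr"]] * cov$egfr
  drug <- ifelse(runif(n) < plogis(lp), "SGLT2i", "DPP4i")

  covdf <- tibble::as_tibble(cov)
  group <- ethnicity_group(ethnicity, pool_mixed_other = TRUE)
  pred_s <- predict_outcome(config$truth_model, covdf, "SGLT2i") +
    lookup_shift(config$shift, group, "SGLT2i")
  pred_d <- predict_outcome(config$truth_model, covdf, "DPP4i") +
    lookup_shift(config$shift, group, "DPP4i")
  true_outcome <- ifelse(drug == "SGLT2i", pred_s, pred_d)
  true_diff <- pred_s - pred_d

  win <- config$outcome_window
  target <- 6
  mp <- config$outcome_month_params
  month <- pmin(pmax(rnorm(n, mp[["mean"]], mp[["sd"]]), win[1]), win[2])
  outcome_value <- true_outcome + rnorm(n, 0, config$noise_sd)

  # decoy records: inside-window decoys strictly farther from the target
  # month than the primary record; outside-window decoys beyond [3, 15]
  n_decoy_in <- rbinom(n, 1, 0.5)
  n_decoy_out <- rbinom(n, 1, 0.5)
  dist <- abs(month - target)
  gap <- 0.25
  left_len <- pmax(0, (target - dist - gap) - win[1])
  right_len <- pmax(0, win[2] - (target + dist + gap))
  tot_len <- left_len + right_len
  n_decoy_in[tot_len <= 0.1] <- 0L
  u_side <- runif(n)
  u_pos <- runif(n)
  decoy_in_month <- ifelse(
    u_side < left_len / pmax(tot_len, 1e-12),
    win[1] + u_pos * left_len,
    (target + dist + gap) + u_pos * right_len
  )
  decoy_in_value <- true_outcome + rnorm(n, 0, config$noise_sd)
  decoy_out_month <- ifelse(runif(n) < 0.5,
                            runif(n, 0.5, win[1] - 0.25),
                            runif(n, win[2] + 0.25, 24))
  decoy_out_value <- true_outcome + rnorm(n, 0, config$noise_sd)

  fmt <- function(m, v) paste0(sprintf("%.8g", m), ":", sprintf("%.10g", v))
  rec <- fmt(month, outcome_value)
  has_in <- n_decoy_in == 1L
  rec[has_in] <- paste(rec[has_in], fmt(decoy_in_month[has_in], decoy_in_value[has_in]),
                       sep = ";")
  has_out <- n_decoy_out == 1L
  rec[has_out] <- paste(rec[has_out], fmt(decoy_out_month[has_out], decoy_out_value[has_out]),
                        sep = ";")

  wp <- config$weight_params
  wi <- match(drug, wp$drug)
  weight_change <- rnorm(n, wp$mean[wi], wp$sd[wi])
  dp <- config$discontinuation_params
  di <- match(drug, dp$drug)
  disc_p <- plogis(dp$intercept[di] + dp$benefit_coef[di] * true_diff)
  discontinued <- runif(n) < disc_p

  insulin_treated <- rep(FALSE, n)
  stable_therapy <- rep(TRUE, n)
  baseline_hba1c <- cov$baseline_hba1c
  egfr <- cov$egfr

  if (config$ineligible_frac > 0) {
    k <- floor(config$ineligible_frac * n)
    if (5 * k > n) stop("ineligible_frac too large for n", call. = FALSE)
    if (k > 0) {
      planted <- matrix(sample.int(n, 5 * k), ncol = 5)
      baseline_hba1c[planted[, 1]] <- 50
      baseline_hba1c[planted[, 2]] <- 125
      egfr[planted[, 3]] <- 40
      insulin_treated[planted[, 4]] <- TRUE
      stable_therapy[planted[, 5]] <- FALSE
    }
  }

  tibble::tibble(
    patient_id = sprintf("P%07d", seq_len(n)),
    drug = drug,
    ethnicity = ethnicity,
    baseline_hba1c = baseline_hba1c,
    age = cov$age,
    bmi = cov$bmi,
    egfr = egfr,
    log_alt = cov$log_alt,
    sex = sex,
    imd_quintile = imd,
    n_current_drugs = n_current_drugs,
    n_ever_classes = n_ever_classes,
    insulin_treated = insulin_treated,
    stable_therapy = stable_therapy,
    hba1c_records = rec,
    weight_change = weight_change,
    discontinued = discontinued,
    true_outcome = true_outcome,
    true_diff = true_diff
  )
}

empty_cohort <- function() {
  tibble::tibble(
    patient_id = character(), drug = character(), ethnicity = character(),
    baseline_hba1c = double(), age = double(), bmi = double(), egfr = double(),
    log_alt = double(), sex = character(), imd_quintile = integer(),
    n_current_drugs = integer(), n_ever_classes = integer(),
    insulin_treated = logical(), stable_therapy = logical(),
    hba1c_records = character(), weight_change = double(),
    discontinued = logical(), true_outcome = double(), true_diff = double()
  )
}

#' Noise-free true differential treatment effect for generated rows
#'
#' The generator's oracle: evaluates the configuration's truth model under
#' both drugs at each row's covariates, adds the configured (ethnicity
#' group, drug) shifts, and returns the difference
#' (SGLT2i minus DPP4i, mmol/mol; negative favours SGLT2i). This is the
#' quantity the downstream calibration machinery is trying to recover.
#'
#' @param config A [sim_config()].
#' @param data Cohort rows (needs the feature columns and `ethnicity`).
#' @return Numeric vector of true differences.
#' @export
true_difference <- function(config, data) {
  stopifnot(inherits(config, "sim_config"))
  group <- ethnicity_group(data$ethnicity, pool_mixed_other = TRUE)
  ps <- predict_outcome(config$truth_model, data, "SGLT2i") +
    lookup_shift(config$shift, group, "SGLT2i")
  pd <- predict_outcome(config$truth_model, data, "DPP4i") +
    lookup_shift(config$shift, group, "DPP4i")
  ps - pd
}
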