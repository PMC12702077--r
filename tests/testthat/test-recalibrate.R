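test_that("intercept-only recalibration is the mean residual", {
  pred <- c(60, 70, 80)
  expect_equal(model2_intercept(pred, pred), 0)
  expect_equal(model2_intercept(pred - 2.6, pred), -2.6)
  expect_equal(model2_intercept(pred + c(1, 2, 3), pred), 2)
  expect_error(model2_intercept(1:3, 1:4), "lengths differ")
  expect_error(model2_intercept(numeric(), numeric()), "at least 1")
})

test_that("intercept-and-slope recalibration matches OLS", {
  pred <- c(55, 60, 72, 80, 91, 100)
  exact <- 3 + 0.9 * pred
  expect_equal(model3_fit(exact, pred), c(a = 3, b = 0.9), tolerance = 1e-12)
  expect_equal(model3_fit(pred, pred), c(a = 0, b = 1), tolerance = 1e-12)

  set.seed(10)
  obs <- 5 + 0.8 * pred + rnorm(6, 0, 2)
  X <- cbind(1, pred)
  beta <- oracle_ols(X, obs)
  expect_equal(unname(model3_fit(obs, pred)), unname(beta), tolerance = 1e-10)

  expect_error(model3_fit(c(1, 2), c(5, 5)), "constant")
})

test_that("profile Gaussian log-likelihood matches its closed form", {
  # residuals (-1, 1), n = 2: RSS/n = 1, LL = -(log(2*pi) + 0 + 1)
  expect_equal(gaussian_loglik(c(0, 2), c(1, 1)), -(log(2 * pi) + 1))
  expect_equal(gaussian_loglik(c(0, 2), c(1, 1)), -2.837877, tolerance = 1e-6)
  # monotone in residual scale
  obs <- c(1, 3, 6, 10); pred <- c(2, 3, 5, 9)
  bigger <- pred + 3 * (obs - pred)  # scales residuals by -2 in magnitude 2
  expect_lt(gaussian_loglik(obs, bigger), gaussian_loglik(obs, pred))
  expect_error(gaussian_loglik(obs, obs), "degenerate")
})

test_that("nesting inequality ll3 >= ll2 >= ll1 holds on random inputs", {
  set.seed(77)
  for (i in 1:25) {
    n <- sample(20:200, 1)
    pred <- rnorm(n, 70, 8)
    obs <- rnorm(1, 0, 3) + runif(1, 0.5, 1.5) * pred + rnorm(n, 0, runif(1, 1, 15))
    ct <- closed_test(obs, pred, m = 5)
    expect_gte(ct$ll3, ct$ll2 - 1e-10)
    expect_gte(ct$ll2, ct$ll1 - 1e-10)
    expect_gte(ct$lr1, -1e-10)
    expect_gte(ct$lr2, -1e-10)
    expect_true(ct$p1 >= 0 && ct$p1 <= 1 && ct$p2 >= 0 && ct$p2 <= 1)
    if (ct$chosen == "Model1") expect_equal(c(ct$a, ct$b), c(0, 1))
    if (ct$chosen == "Model2") expect_equal(ct$b, 1)
  }
})

test_that("decision rules select the planted update", {
  # null data -> Model1 with (a, b) = (0, 1) (literal df makes this stable)
  set.seed(21)
  pred <- rnorm(3000, 70, 7)
  obs <- pred + rnorm(3000, 0, 12)
  ct0 <- closed_test(obs, pred, m = 13)
  expect_equal(ct0$chosen, "Model1")
  expect_equal(c(ct0$a, ct0$b), c(0, 1))

  # planted intercept shift -3 -> Model2, a near -3
  set.seed(22)
  pred <- rnorm(5000, 70, 7)
  obs <- pred - 3 + rnorm(5000, 0, 12)
  ct2 <- closed_test(obs, pred, m = 13, df_convention = "nesting")
  expect_equal(ct2$chosen, "Model2")
  expect_lt(abs(ct2$a - (-3)), 3 * 12 / sqrt(5000))
  expect_equal(ct2$b, 1)

  # planted slope: obs = 5 + 0.7 pred + noise -> Model3 at large n
  set.seed(23)
  pred <- rnorm(8000, 70, 7)
  obs <- 5 + 0.7 * pred + rnorm(8000, 0, 12)
  ct3 <- closed_test(obs, pred, m = 13, df_convention = "nesting")
  expect_equal(ct3$chosen, "Model3")
  expect_lt(abs(ct3$b - 0.7), 0.1)
})

test_that("literal and nesting df conventions differ only in the reference", {
  set.seed(31)
  pred <- rnorm(500, 70, 7)
  obs <- pred - 2 + rnorm(500, 0, 12)
  lit <- closed_test(obs, pred, m = 13, df_convention = "literal")
  nest <- closed_test(obs, pred, m = 13, df_convention = "nesting")
  expect_equal(lit$lr1, nest$lr1)
  expect_equal(lit$lr2, nest$lr2)
  expect_equal(c(lit$df1, lit$df2), c(13, 14))
  expect_equal(c(nest$df1, nest$df2), c(1, 1))
  expect_gt(lit$p1, nest$p1)  # same statistic against a wider reference
})

test_that("closed test validates preconditions", {
  expect_error(closed_test(1:10, 1:10 + 0.5, m = 0), "positive integer")
  expect_error(closed_test(1:5, 1:5 + 0.5, m = 13), "n > m \\+ 2")
  expect_error(closed_test(1:30, (1:30) / 2, m = 5, alpha = 1.5), "alpha")
})

test_that("apply_update composes correctly with the decisions", {
  pred <- c(10, 20)
  expect_equal(apply_update(pred, list(a = 0, b = 1)), pred)
  expect_equal(apply_update(pred, list(a = -0.9, b = 1)), pred - 0.9)
  expect_equal(apply_update(pred, list(a = 2, b = 0.5)), c(7, 12))
  # after a Model 2 update the mean residual is zero to machine precision
  set.seed(41)
  pred <- rnorm(400, 70, 7)
  obs <- pred - 2.2 + rnorm(400, 0, 10)
  ct <- closed_test(obs, pred, m = 13, df_convention = "nesting")
  updated <- apply_update(pred, ct)
  expect_equal(model2_intercept(obs, updated), 0, tolerance = 1e-10)
})

test_that("tidy and glance expose the decision as one-row tibbles", {
  set.seed(51)
  pred <- rnorm(300, 70, 7)
  ct <- closed_test(pred + rnorm(300, 0, 10), pred, m = 13,
                    ethnicity = "White", drug = "DPP4i")
  td <- tidy(ct)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 1L)
  expect_equal(td$ethnicity, "White")
  expect_true(all(c("lr1", "lr2", "p1", "p2", "df1", "df2", "m", "n") %in% names(td)))
  gl <- glance(ct)
  expect_equal(gl$chosen, ct$chosen)
})

test_that("per-cell recalibration covers every retained cell and skips small ones", {
  sc <- sim_config(n = 20000, seed = 61)
  co <- build_cohort(simulate_cohort(sc))
  dec <- recalibrate_cohort(co, sc$truth_model, df_convention = "nesting")
  expect_equal(nrow(dec), 8L)
  expect_setequal(unique(dec$ethnicity), ethnicity_groups(TRUE))
  expect_setequal(unique(dec$drug), drug_levels())
  expect_true(all(dec$m == 13L))
  # huge min_n forces all cells to be skipped with warnings
  w <- capture_warnings(dec2 <- recalibrate_cohort(co, sc$truth_model, min_n = 1e6))
  expect_length(w, 8L)
  expect_true(all(grepl("skipped", w)))
  expect_equal(nrow(dec2), 0L)
})
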