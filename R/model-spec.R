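#' Clinical features usable as model predictors
#'
#' The treatment selection model predicts 6-month HbA1c from five routinely
#' measured clinical features. These are the only feature names a
#' [model_spec()] may reference.
#'
#' @format Character vector of length five.
#' @export
model_features <- c("baseline_hba1c", "age", "bmi", "egfr", "log_alt")

#' Construct a two-drug treatment selection model specification
#'
#' A `model_spec` holds everything needed to evaluate a linear 6-month HbA1c
#' prediction model under either drug: an intercept, main-effect terms on
#' restricted-cubic-spline (RCS) basis columns of the five clinical features,
#' a main effect for the SGLT2i indicator, and drug-by-feature interaction
#' terms. Predictions under DPP4i use only the intercept and main-effect
#' terms; predictions under SGLT2i additionally add the drug main effect and
#' interactions evaluated at the same covariates.
#'
#' @param intercept Model intercept, mmol/mol.
#' @param terms Data frame with columns `feature` (one of [model_features]),
#'   `basis` (1 = linear column, 2 = restricted cubic column) and `coef`.
#' @param drug_main Coefficient on the SGLT2i indicator, mmol/mol.
#' @param drug_interactions Data frame with the same columns as `terms`,
#'   added only under SGLT2i.
#' @param knots Named list; for every feature used with `basis = 2` (and any
#'   feature you want splined) a strictly increasing numeric vector of three
#'   knot locations on the feature's own scale.
#'
#' @return An object of class `model_spec`.
#' @seealso [predict_outcome()], [predicted_difference()], [read_model_spec()]
#' @export
model_spec <- function(intercept = 0,
                       terms = empty_terms(),
                       drug_main = 0,
                       drug_interactions = empty_terms(),
                       knots = list()) {
  terms <- as_terms(terms, "terms")
  drug_interactions <- as_terms(drug_interactions, "drug_interactions")
  stopifnot(is.numeric(intercept), length(intercept) == 1L, is.finite(intercept),
            is.numeric(drug_main), length(drug_main) == 1L, is.finite(drug_main))
  if (!is.list(knots)) stop("`knots` must be a named list of 3-knot vectors", call. = FALSE)
  for (f in names(knots)) {
    k <- knots[[f]]
    if (!is.numeric(k) || length(k) != 3L || any(!is.finite(k)) || any(diff(k) <= 0)) {
      stop("knots for feature '", f, "' must be 3 strictly increasing finite values",
           call. = FALSE)
    }
  }
  needs_knots <- unique(c(terms$feature[terms$basis == 2L],
                          drug_interactions$feature[drug_interactions$basis == 2L]))
  missing_k <- setdiff(needs_knots, names(knots))
  if (length(missing_k) > 0) {
    stop("nonlinear terms reference features without knots: ",
         paste(missing_k, collapse = ", "), call. = FALSE)
  }
  structure(
    list(intercept = intercept, terms = terms, drug_main = drug_main,
         drug_interactions = drug_interactions, knots = knots),
    class = "model_spec"
  )
}

empty_terms <- function() {
  tibble::tibble(feature = character(), basis = integer(), coef = double())
}

as_terms <- function(x, what) {
  x <- tibble::as_tibble(x)
  if (nrow(x) == 0 && !all(c("feature", "basis", "coef") %in% names(x))) {
    return(empty_terms())
  }
  if (!all(c("feature", "basis", "coef") %in% names(x))) {
    stop("`", what, "` must have columns feature, basis, coef", call. = FALSE)
  }
  x$basis <- as.integer(x$basis)
  bad <- setdiff(x$feature, model_features)
  if (length(bad) > 0) {
    stop("`", what, "` references unknown features: ",
         paste(unique(bad), collapse = ", "), call. = FALSE)
  }
  if (any(!x$basis %in% c(1L, 2L))) {
    stop("`", what, "` basis indices must be 1 (linear) or 2 (cubic)", call. = FALSE)
  }
  if (any(!is.finite(x$coef))) stop("`", what, "` coefficients must be finite", call. = FALSE)
  x[c("feature", "basis", "coef")]
}

#' @export
print.model_spec <- function(x, ...) {
  cat("<model_spec>\n")
  cat("  intercept:", format(x$intercept), "mmol/mol\n")
  cat("  main-effect terms:", nrow(x$terms), "\n")
  cat("  drug main effect (SGLT2i):", format(x$drug_main), "\n")
  cat("  drug interactions:", nrow(x$drug_interactions), "\n")
  cat("  splined features:", paste(names(x$knots), collapse = ", "), "\n")
  cat("  non-intercept parameters (m):", n_model_params(x), "\n")
  invisible(x)
}

#' Number of estimated non-intercept parameters in a model
#'
#' Counts every coefficient except the intercept: all main-effect terms, the
#' drug main effect, and all drug interactions. This is the `m` used as
#' degrees of freedom by the closed testing procedure.
#'
#' @param spec A [model_spec()].
#' @return Integer count.
#' @export
n_model_params <- function(spec) {
  stopifnot(inherits(spec, "model_spec"))
  nrow(spec$terms) + 1L + nrow(spec$drug_interactions)
}

#' Restricted cubic spline basis with three knots
#'
#' Returns the two basis columns of a 3-knot restricted cubic spline:
#' column 1 is the identity (linear) term and column 2 the restricted
#' truncated-power cubic term, constrained to be linear beyond the boundary
#' knots and divided by the squared knot span `(k3 - k1)^2` so that its
#' coefficient stays on the outcome scale.
#'
#' The function is continuous with continuous first and second derivatives
#' everywhere, exactly zero for `x <= k1`, and exactly linear for `x >= k3`.
#'
#' @param x Numeric vector.
#' @param knots Strictly increasing numeric vector of length 3.
#' @return Numeric matrix with `length(x)` rows and 2 columns.
#' @export
#' @examples
#' rcs_basis(c(0, 0.5, 1.5, 2.5), knots = c(0, 1, 2))
rcs_basis <- function(x, knots) {
  if (!is.numeric(knots) || length(knots) != 3L || any(diff(knots) <= 0)) {
    stop("`knots` must be 3 strictly increasing values", call. = FALSE)
  }
  k1 <- knots[1]; k2 <- knots[2]; k3 <- knots[3]
  cub <- function(u) pmax(u, 0)^3
  nl <- (cub(x - k1) -
           cub(x - k2) * (k3 - k1) / (k3 - k2) +
           cub(x - k3) * (k2 - k1) / (k3 - k2)) / (k3 - k1)^2
  cbind(linear = x, cubic = nl)
}

basis_column <- function(data, feature, basis, knots) {
  x <- data[[feature]]
  if (is.null(x)) stop("data lacks predictor column '", feature, "'", call. = FALSE)
  if (basis == 1L) return(x)
  rcs_basis(x, knots[[feature]])[, 2L]
}

#' Predict 6-month HbA1c under a given drug
#'
#' Evaluates the linear predictor of a [model_spec()] for each row of a
#' cohort table under the stated drug. All five clinical features must be
#' present and non-missing (the model is a complete-case model).
#'
#' @param spec A [model_spec()].
#' @param data Data frame with the feature columns named as in
#'   [model_features].
#' @param drug `"SGLT2i"` or `"DPP4i"`; either a single value or a vector of
#'   length `nrow(data)` (e.g. the received drug).
#' @return Numeric vector of predicted 6-month HbA1c, mmol/mol.
#' @export
predict_outcome <- function(spec, data, drug) {
  stopifnot(inherits(spec, "model_spec"))
  data <- as.data.frame(data)
  n <- nrow(data)
  drug <- check_drug(drug, n)
  used <- unique(c(spec$terms$feature, spec$drug_interactions$feature))
  for (f in used) {
    if (is.null(data[[f]])) stop("data lacks predictor column '", f, "'", call. = FALSE)
    if (anyNA(data[[f]])) {
      stop("missing values in predictor '", f, "': the model requires complete cases",
           call. = FALSE)
    }
  }
  lp <- rep(spec$intercept, n)
  for (i in seq_len(nrow(spec$terms))) {
    tm <- spec$terms[i, ]
    lp <- lp + tm$coef * basis_column(data, tm$feature, tm$basis, spec$knots)
  }
  sglt <- as.numeric(drug == "SGLT2i")
  drug_lp <- rep(spec$drug_main, n)
  for (i in seq_len(nrow(spec$drug_interactions))) {
    tm <- spec$drug_interactions[i, ]
    drug_lp <- drug_lp + tm$coef * basis_column(data, tm$feature, tm$basis, spec$knots)
  }
  lp + sglt * drug_lp
}

check_drug <- function(drug, n) {
  drug <- as.character(drug)
  if (!length(drug) %in% c(1L, n)) {
    stop("`drug` must be length 1 or nrow(data)", call. = FALSE)
  }
  if (any(!drug %in% drug_levels())) {
    stop("`drug` values must be in {", paste(drug_levels(), collapse = ", "), "}",
         call. = FALSE)
  }
  if (length(drug) == 1L) drug <- rep(drug, n)
  drug
}

#' Predicted differential treatment effect
#'
#' Evaluates the model under both drugs on identical covariates and returns
#' the per-row predicted difference. Negative values mean a predicted
#' 6-month HbA1c benefit on SGLT2i (lower achieved HbA1c than on DPP4i);
#' positive values favour DPP4i.
#'
#' @inheritParams predict_outcome
#' @return A tibble with columns `pred_sglt2i`, `pred_dpp4i` and
#'   `diff = pred_sglt2i - pred_dpp4i` (mmol/mol).
#' @export
predicted_difference <- function(spec, data) {
  ps <- predict_outcome(spec, data, "SGLT2i")
  pd <- predict_outcome(spec, data, "DPP4i")
  tibble::tibble(pred_sglt2i = ps, pred_dpp4i = pd, diff = ps - pd)
}

#' Default stand-in treatment selection model
#'
#' A synthetic, plausibly signed stand-in for a published SGLT2i-DPP4i
#' treatment selection model: it is *not* a fitted or published model, but a
#' fixed specification used both as the simulation ground truth and as the
#' "original model" under validation in examples and tests. Signs follow the
#' clinical narrative: higher baseline HbA1c, higher BMI, higher eGFR and
#' younger age shift the predicted benefit towards SGLT2i. Knots sit at
#' round values near the 10th/50th/90th percentiles of the simulated
#' covariate distributions.
#'
#' @return A [model_spec()] with 13 non-intercept parameters.
#' @export
default_model_spec <- function() {
  model_spec(
    intercept = 10.4,
    terms = tibble::tribble(
      ~feature,         ~basis, ~coef,
      "baseline_hba1c", 1L,      0.62,
      "baseline_hba1c", 2L,      1.50,
      "age",            1L,     -0.06,
      "bmi",            1L,      0.08,
      "egfr",           1L,     -0.025,
      "egfr",           2L,      0.80,
      "log_alt",        1L,      1.10
    ),
    drug_main = 19.8,
    drug_interactions = tibble::tribble(
      ~feature,         ~basis, ~coef,
      "baseline_hba1c", 1L,     -0.15,
      "bmi",            1L,     -0.25,
      "bmi",            2L,     -0.50,
      "egfr",           1L,     -0.12,
      "age",            1L,      0.12
    ),
    knots = list(
      baseline_hba1c = c(57, 72, 92),
      age            = c(46, 61, 75),
      bmi            = c(25, 32, 41),
      egfr           = c(68, 91, 112),
      log_alt        = c(2.7, 3.3, 4.0)
    )
  )
}

#' Read / write a model specification
#'
#' `model_spec` objects serialize to a plain YAML document with explicit
#' knot arrays, so a model can be shipped or edited as text. The round trip
#' preserves predictions to machine precision.
#'
#' @param path File path of the YAML document.
#' @return `read_model_spec()` returns a [model_spec()];
#'   `write_model_spec()` returns `path` invisibly.
#' @export
read_model_spec <- function(path) {
  doc <- yaml::read_yaml(path)
  for (field in c("intercept", "drug_main", "knots")) {
    if (is.null(doc[[field]])) {
      stop("model file '", path, "': missing field '", field, "'", call. = FALSE)
    }
  }
  model_spec(
    intercept = as.numeric(doc$intercept),
    terms = terms_from_yaml(doc$terms, path, "terms"),
    drug_main = as.numeric(doc$drug_main),
    drug_interactions = terms_from_yaml(doc$drug_interactions, path, "drug_interactions"),
    knots = lapply(doc$knots, as.numeric)
  )
}

terms_from_yaml <- function(entries, path, what) {
  if (is.null(entries) || length(entries) == 0) return(empty_terms())
  rows <- lapply(seq_along(entries), function(i) {
    e <- entries[[i]]
    if (is.null(e$feature) || is.null(e$basis) || is.null(e$coef)) {
      stop("model file '", path, "': ", what, " entry ", i,
           " must have feature, basis and coef", call. = FALSE)
    }
    tibble::tibble(feature = as.character(e$feature),
                   basis = as.integer(e$basis),
                   coef = as.numeric(e$coef))
  })
  dplyr::bind_rows(rows)
}

#' @rdname read_model_spec
#' @param spec A [model_spec()].
#' @export
write_model_spec <- function(spec, path) {
  stopifnot(inherits(spec, "model_spec"))
  terms_to_yaml <- function(tt) {
    lapply(seq_len(nrow(tt)), function(i) {
      list(feature = tt$feature[i], basis = tt$basis[i], coef = tt$coef[i])
    })
  }
  doc <- list(
    intercept = spec$intercept,
    terms = terms_to_yaml(spec$terms),
    drug_main = spec$drug_main,
    drug_interactions = terms_to_yaml(spec$drug_interactions),
    knots = spec$knots
  )
  yaml::write_yaml(doc, path, precision = 15)
  invisible(path)
}
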