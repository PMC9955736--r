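#' Evaluate a calibration model on calibration and prediction sets
#'
#' Computes the standard chemometric report: Rc and Rp (Pearson correlation
#' between predicted and reference values on the calibration and prediction
#' sets), RMSEC and RMSEP (root-mean-square errors, mg/100 g for TVB-N),
#' and RPD, the standard deviation of the prediction-set reference values
#' (n - 1 denominator) divided by RMSEP.
#'
#' @param model A fitted `pls_model` or `svr_model` (anything with a
#'   `predict` method returning responses on the original scale).
#' @param x_cal,y_cal Calibration predictors and reference values.
#' @param x_pred,y_pred Prediction-set predictors and reference values.
#' @param label Optional model label for reports.
#' @return A `csa_evaluation` object.
#' @export
evaluate_model <- function(model, x_cal, y_cal, x_pred, y_pred,
                           label = class(model)[1]) {
  if (length(y_cal) == 0 || length(y_pred) == 0) {
    abort("Calibration and prediction sets must be non-empty.")
  }
  if (sd(y_cal) == 0 || sd(y_pred) == 0) {
    abort("Reference values have zero variance; correlation is undefined.")
  }
  pc <- predict(model, x_cal)
  pp <- predict(model, x_pred)
  rmsep <- rmse(y_pred, pp)
  sd_pred <- sd(y_pred)
  settings <- if (inherits(model, "pls_model")) {
    list(n_lv = model$n_lv)
  } else if (inherits(model, "svr_model")) {
    list(gamma = model$gamma, cost = model$cost, epsilon = model$epsilon)
  } else {
    list()
  }
  structure(
    list(
      label = label,
      Rc = cor(pc, y_cal), RMSEC = rmse(y_cal, pc),
      Rp = cor(pp, y_pred), RMSEP = rmsep,
      SD_pred = sd_pred,
      RPD = sd_pred / rmsep,
      n_cal = length(y_cal), n_pred = length(y_pred),
      n_variables = ncol(feature_matrix(x_cal)),
      settings = settings,
      predictions = tibble::tibble(
        set = rep(c("calibration", "prediction"), c(length(y_cal), length(y_pred))),
        reference = c(y_cal, y_pred),
        predicted = c(pc, pp)
      )
    ),
    class = "csa_evaluation"
  )
}

#' @export
print.csa_evaluation <- function(x, ...) {
  cat(sprintf(
    "<csa_evaluation> %s: Rc %.3f RMSEC %.3f | Rp %.3f RMSEP %.3f | RPD %.3f (%s)\n",
    x$label, x$Rc, x$RMSEC, x$Rp, x$RMSEP, x$RPD, classify_rpd(x$RPD)
  ))
  invisible(x)
}

#' @exportS3Method
tidy.csa_evaluation <- function(x, ...) x$predictions

#' @exportS3Method
glance.csa_evaluation <- function(x, ...) {
  tibble::tibble(
    model = x$label,
    n_variables = x$n_variables,
    n_lv = x$settings$n_lv %||% NA_integer_,
    gamma = x$settings$gamma %||% NA_real_,
    cost = x$settings$cost %||% NA_real_,
    Rc = x$Rc, RMSEC = x$RMSEC,
    Rp = x$Rp, RMSEP = x$RMSEP, RPD = x$RPD,
    rpd_class = classify_rpd(x$RPD)
  )
}

#' Classify a model's RPD
#'
#' RPD at least 1.50 marks a practicable model and at least 2.00 a stable
#' one; anything below 1.50 is inadequate.
#'
#' @param rpd Numeric RPD value(s).
#' @return Character vector in `{"inadequate", "practicable", "stable"}`.
#' @export
classify_rpd <- function(rpd) {
  if (any(!is.finite(rpd))) abort("`rpd` must be finite.")
  dplyr::case_when(
    rpd >= 2.00 ~ "stable",
    rpd >= 1.50 ~ "practicable",
    .default = "inadequate"
  )
}

#' Wald-Wolfowitz runs test on residual signs
#'
#' Counts sign runs in the residual sequence (exact zeros dropped) and
#' compares against the large-sample normal approximation:
#' `mu = 2 n1 n2 / (n1 + n2) + 1`,
#' `sigma^2 = 2 n1 n2 (2 n1 n2 - n1 - n2) / ((n1 + n2)^2 (n1 + n2 - 1))`,
#' `z = (R - mu) / sigma`. `|z| > 1.96` flags a nonlinear relationship at
#' the 0.05 level — the diagnostic that motivates switching from PLS to a
#' nonlinear SVR calibration.
#'
#' @param residuals Numeric residual vector (reference minus predicted, in
#'   model order).
#' @return A `runs_test` object: `z`, runs count `R`, `n_positive`,
#'   `n_negative`, and `nonlinear` flag.
#' @export
runs_test <- function(residuals) {
  s <- sign(residuals)
  s <- s[s != 0]
  n1 <- sum(s > 0)
  n2 <- sum(s < 0)
  if (n1 == 0 || n2 == 0) {
    abort("All residuals share one sign; the runs-test z is undefined.")
  }
  r <- 1L + sum(diff(s) != 0)
  nn <- n1 + n2
  mu <- 2 * n1 * n2 / nn + 1
  sigma2 <- 2 * n1 * n2 * (2 * n1 * n2 - nn) / (nn^2 * (nn - 1))
  z <- (r - mu) / sqrt(sigma2)
  structure(
    list(
      z = z, runs = r, n_positive = n1, n_negative = n2,
      mu = mu, sigma = sqrt(sigma2),
      critical = 1.96,
      nonlinear = abs(z) > 1.96
    ),
    class = "runs_test"
  )
}

#' @export
print.runs_test <- function(x, ...) {
  cat(sprintf(
    "<runs_test> R = %d (n+ = %d, n- = %d), z = %.3f -> %s\n",
    x$runs, x$n_positive, x$n_negative, x$z,
    if (x$nonlinear) "nonlinear (|z| > 1.96)" else "no nonlinearity flagged"
  ))
  invisible(x)
}

#' @exportS3Method
glance.runs_test <- function(x, ...) {
  tibble::tibble(
    z = x$z, runs = x$runs, n_positive = x$n_positive,
    n_negative = x$n_negative, critical = x$critical,
    nonlinear = x$nonlinear
  )
}

#' TVB-N concentration from a titration record
#'
#' Steam-distillation titration: `X = (v1 - v2) * c * 14 / (m *
#' aliquot_factor) * 100` mg per 100 g, where 14 is the molar mass of
#' nitrogen (mg/mmol). The default `aliquot_factor = 5/100` follows the
#' printed formula; note that a 10 mL aliquot of a 100 mL filtrate would
#' imply 10/100, so the factor is exposed rather than hard-coded.
#'
#' @param v1 HCl volume for the sample titration (mL).
#' @param v2 HCl volume for the blank (mL).
#' @param c HCl concentration (mol/L), default 0.1.
#' @param m Sample mass (g), default 10.
#' @param aliquot_factor Dimensionless aliquot share (default `5/100`).
#' @return TVB-N in mg/100 g (vectorised).
#' @export
tvbn_concentration <- function(v1, v2, c = 0.1, m = 10, aliquot_factor = 5 / 100) {
  if (any(v2 < 0) || any(v1 < v2)) abort("Volumes must satisfy v1 >= v2 >= 0.")
  if (any(c <= 0) || any(m <= 0) || any(aliquot_factor <= 0)) {
    abort("`c`, `m` and `aliquot_factor` must be positive.")
  }
  (v1 - v2) * c * 14 / (m * aliquot_factor) * 100
}
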