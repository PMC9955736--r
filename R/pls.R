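#' Fit a PLS1 calibration model
#'
#' Partial least squares regression for a single response, computed by
#' NIPALS-style deflation (for one response the weight vector per component
#' is closed-form, `w = X'y / ||X'y||`, so no inner iteration is needed).
#' Predictors are autoscaled (centred, unit variance; zero-variance columns
#' centred only) and the response centred before fitting; the regression
#' vector is also reported on the original predictor scale.
#'
#' @param x Feature table or numeric predictor matrix.
#' @param y Response vector (mg/100 g for TVB-N); taken from a table's
#'   `tvbn` column when omitted.
#' @param n_lv Number of latent variables, `1 <= n_lv <= min(n - 1, p)`.
#' @param scale Autoscale predictors to unit variance (default `TRUE`);
#'   with `FALSE` they are centred only, preserving relative amplitudes.
#' @return A `pls_model` object with weights, scores, loadings, the
#'   regression vector and the stored scaling.
#' @export
pls_fit <- function(x, y = NULL, n_lv, scale = TRUE) {
  x <- feature_matrix(x)
  if (is.null(y)) abort("`y` is required.")
  x <- check_xy(x, y)
  n <- nrow(x)
  p <- ncol(x)
  if (n_lv < 1 || n_lv > min(n - 1, p)) {
    abort(sprintf("`n_lv` must lie in 1..min(n - 1, p) = %d.", min(n - 1, p)))
  }
  sc <- if (scale) {
    autoscale(x)
  } else {
    ctr <- colMeans(x)
    list(x = sweep(x, 2, ctr, "-"), center = ctr, scale = rep(1, p))
  }
  xs <- sc$x
  y_center <- mean(y)
  ys <- y - y_center

  W <- matrix(0, p, n_lv)
  P <- matrix(0, p, n_lv)
  Tm <- matrix(0, n, n_lv)
  q <- numeric(n_lv)
  Xd <- xs
  yd <- ys
  a_used <- 0L
  for (a in seq_len(n_lv)) {
    w <- crossprod(Xd, yd)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) break # response variance exhausted
    w <- w / nw
    t <- Xd %*% w
    tt <- sum(t^2)
    if (tt < 1e-12) break
    pvec <- crossprod(Xd, t) / tt
    qa <- sum(yd * t) / tt
    Xd <- Xd - t %*% t(pvec)
    yd <- yd - qa * t
    W[, a] <- w
    P[, a] <- pvec
    Tm[, a] <- t
    q[a] <- qa
    a_used <- a
  }
  if (a_used == 0L) {
    beta_s <- numeric(p)
  } else {
    idx <- seq_len(a_used)
    # beta = W (P'W)^-1 q on the scaled space
    beta_s <- W[, idx, drop = FALSE] %*%
      solve(
        crossprod(P[, idx, drop = FALSE], W[, idx, drop = FALSE]),
        q[idx]
      )
    beta_s <- as.vector(beta_s)
  }
  beta_orig <- beta_s / sc$scale
  model <- structure(
    list(
      n_lv = as.integer(n_lv), n_lv_used = a_used,
      coefficients = stats::setNames(beta_s, colnames(x)),
      coefficients_original = stats::setNames(beta_orig, colnames(x)),
      intercept = y_center - sum(beta_orig * sc$center),
      weights = W, loadings = P, scores = Tm, q = q,
      x_center = sc$center, x_scale = sc$scale, y_center = y_center,
      n = n, p = p
    ),
    class = "pls_model"
  )
  model$fitted <- as.vector(predict(model, x))
  model
}

#' @export
predict.pls_model <- function(object, newdata, ...) {
  x <- feature_matrix(newdata)
  as.vector(x %*% object$coefficients_original + object$intercept)
}

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf(
    "<pls_model> %d latent variables (%d used), %d predictors, n = %d\n",
    x$n_lv, x$n_lv_used, x$p, x$n
  ))
  invisible(x)
}

#' @exportS3Method
tidy.pls_model <- function(x, ...) {
  tibble::tibble(
    term = c("(Intercept)", names(x$coefficients_original)),
    estimate = c(x$intercept, unname(x$coefficients_original))
  )
}

#' @exportS3Method
glance.pls_model <- function(x, ...) {
  tibble::tibble(n_lv = x$n_lv, n = x$n, p = x$p)
}

# k-fold cross-validated RMSE of a model-fitting function.
# fit_fun(x_train, y_train) -> object with a predict method.
rmsecv <- function(x, y, folds, fit_fun) {
  press <- 0
  for (idx in folds) {
    fit <- fit_fun(x[-idx, , drop = FALSE], y[-idx])
    pred <- predict(fit, x[idx, , drop = FALSE])
    press <- press + sum((y[idx] - pred)^2)
  }
  sqrt(press / length(y))
}

#' Choose the number of PLS latent variables by cross-validation
#'
#' @param x Feature table or predictor matrix.
#' @param y Response vector.
#' @param max_nlv Largest number of latent variables to consider (clipped
#'   to what the fold training sets support).
#' @param k Folds (default 5).
#' @param seed Fold-shuffle seed.
#' @return List with `best` (smallest `n_lv` attaining the minimum RMSECV)
#'   and `curve`, a tibble of `n_lv` vs `rmsecv`.
#' @export
select_nlv <- function(x, y = NULL, max_nlv = 10, k = 5, seed = 1) {
  x <- feature_matrix(x)
  if (is.null(y)) abort("`y` is required.")
  if (max_nlv < 1) abort("`max_nlv` must be >= 1.")
  n <- nrow(x)
  folds <- kfold_indices(n, k, seed)
  min_train <- min(vapply(folds, function(f) n - length(f), 0L))
  amax <- min(max_nlv, min_train - 1, ncol(x))
  rms <- vapply(seq_len(amax), function(a) {
    rmsecv(x, y, folds, function(xt, yt) pls_fit(xt, yt, n_lv = a))
  }, 0)
  list(
    best = which.min(rms), # which.min returns the first (smallest) minimum
    curve = tibble::tibble(n_lv = seq_len(amax), rmsecv = rms)
  )
}
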