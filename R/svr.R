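#' Fit an epsilon-SVR calibration with RBF kernel
#'
#' Support vector regression with the epsilon-insensitive loss and the
#' radial-basis kernel `exp(-g * ||xi - xj||^2)`, the convention under which
#' small kernel widths (g well below 1) are typical for autoscaled
#' 90-variable fingerprints. Predictors are autoscaled and the response
#' standardised before solving; predictions are returned on the original
#' response scale. The quadratic programme is solved by libsvm via
#' \pkg{e1071}.
#'
#' @param x Feature table or predictor matrix.
#' @param y Response vector.
#' @param gamma RBF width g (> 0).
#' @param cost Penalty c (> 0).
#' @param epsilon Insensitivity tube on the standardised response
#'   (default 0.1).
#' @return An `svr_model` object.
#' @export
svr_fit <- function(x, y = NULL, gamma, cost, epsilon = 0.1) {
  x <- feature_matrix(x)
  if (is.null(y)) abort("`y` is required.")
  x <- check_xy(x, y)
  if (gamma <= 0 || cost <= 0) abort("`gamma` and `cost` must be > 0.")
  if (epsilon < 0) abort("`epsilon` must be >= 0.")
  sc <- autoscale(x)
  y_center <- mean(y)
  y_scale <- sd(y)
  if (!is.finite(y_scale) || y_scale < .Machine$double.eps) y_scale <- 1
  fit <- e1071::svm(
    x = sc$x, y = (y - y_center) / y_scale,
    type = "eps-regression", kernel = "radial",
    gamma = gamma, cost = cost, epsilon = epsilon,
    scale = FALSE
  )
  structure(
    list(
      fit = fit, gamma = gamma, cost = cost, epsilon = epsilon,
      x_center = sc$center, x_scale = sc$scale,
      y_center = y_center, y_scale = y_scale,
      n = nrow(x), p = ncol(x)
    ),
    class = "svr_model"
  )
}

#' @export
predict.svr_model <- function(object, newdata, ...) {
  x <- apply_scaling(feature_matrix(newdata), object$x_center, object$x_scale)
  as.vector(predict(object$fit, x)) * object$y_scale + object$y_center
}

#' @export
print.svr_model <- function(x, ...) {
  cat(sprintf(
    "<svr_model> RBF eps-SVR: g = %g, c = %g, epsilon = %g, %d SVs\n",
    x$gamma, x$cost, x$epsilon, x$fit$tot.nSV
  ))
  invisible(x)
}

#' @exportS3Method
glance.svr_model <- function(x, ...) {
  tibble::tibble(
    gamma = x$gamma, cost = x$cost, epsilon = x$epsilon,
    n_sv = x$fit$tot.nSV, n = x$n, p = x$p
  )
}

#' Grid search for the SVR hyperparameters (g, c)
#'
#' Exhaustive evaluation of every (g, c) pair by k-fold cross-validated
#' RMSE; ties are resolved toward the smallest cost, then the smallest
#' gamma. Powers of two spanning 2^-8..2^8 are the default grid.
#'
#' @inheritParams svr_fit
#' @param g_grid,c_grid Candidate values for g and c.
#' @param k Folds (default 5).
#' @param seed Fold-shuffle seed.
#' @return An `svr_grid` object: tibble of the full grid with `rmsecv`,
#'   plus the best pair.
#' @export
grid_search_svr <- function(x, y = NULL, g_grid = 2^(-8:8), c_grid = 2^(-8:8),
                            k = 5, epsilon = 0.1, seed = 1) {
  x <- feature_matrix(x)
  if (is.null(y)) abort("`y` is required.")
  if (length(g_grid) == 0 || length(c_grid) == 0) abort("Grids must be non-empty.")
  folds <- kfold_indices(nrow(x), k, seed)
  grid <- tidyr::expand_grid(gamma = sort(g_grid), cost = sort(c_grid))
  grid$rmsecv <- purrr::map2_dbl(grid$gamma, grid$cost, function(g, cc) {
    rmsecv(x, y, folds, function(xt, yt) {
      svr_fit(xt, yt, gamma = g, cost = cc, epsilon = epsilon)
    })
  })
  best <- grid |>
    dplyr::filter(.data$rmsecv == min(.data$rmsecv)) |>
    dplyr::arrange(.data$cost, .data$gamma) |>
    dplyr::slice(1)
  structure(
    list(
      grid = grid,
      best_gamma = best$gamma, best_cost = best$cost,
      best_rmsecv = best$rmsecv, epsilon = epsilon, k = k
    ),
    class = "svr_grid"
  )
}

#' @export
print.svr_grid <- function(x, ...) {
  cat(sprintf(
    "<svr_grid> %d (g, c) pairs; best g = %g, c = %g (RMSECV %.4g)\n",
    nrow(x$grid), x$best_gamma, x$best_cost, x$best_rmsecv
  ))
  invisible(x)
}

#' @exportS3Method
tidy.svr_grid <- function(x, ...) x$grid

#' @exportS3Method
glance.svr_grid <- function(x, ...) {
  tibble::tibble(
    best_gamma = x$best_gamma, best_cost = x$best_cost,
    best_rmsecv = x$best_rmsecv, n_pairs = nrow(x$grid)
  )
}
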