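test_that("full-rank PLS equals ordinary least squares", {
  withr::with_seed(31, {
    x <- matrix(rnorm(10 * 4), 10, 4)
    y <- rnorm(10)
  })
  fit <- pls_fit(x, y, n_lv = 4)
  ols <- unname(coef(lm(y ~ x)))
  expect_equal(fit$intercept, ols[1], tolerance = 1e-8)
  expect_equal(unname(fit$coefficients_original), ols[-1], tolerance = 1e-8)
})

test_that("rank-one structure is captured by a single latent variable", {
  withr::with_seed(32, {
    t1 <- rnorm(20)
    x <- t1 %o% runif(6)
    y <- 2 * t1 + 1
  })
  fit <- pls_fit(x, y, n_lv = 1)
  expect_lt(rmse(y, fit$fitted), 1e-8)
})

test_that("constant responses give zero coefficients", {
  withr::with_seed(33, {
    x <- matrix(rnorm(12 * 3), 12, 3)
  })
  fit <- pls_fit(x, rep(7, 12), n_lv = 2)
  expect_equal(unname(fit$coefficients), rep(0, 3))
  expect_equal(fit$intercept, 7)
  expect_error(pls_fit(x, rep(7, 12), n_lv = 12), "n_lv")
})

test_that("latent-variable selection finds a known factor dimension", {
  hits <- 0
  for (s in 1:15) {
    withr::with_seed(300 + s, {
      scores <- matrix(rnorm(60 * 3), 60, 3)
      load <- matrix(rnorm(3 * 12), 3, 12)
      # response noise dominates predictor noise, so components beyond the
      # true dimension only fit fold noise and RMSECV rises past 3
      x <- scores %*% load + matrix(rnorm(60 * 12, 0, 0.01), 60, 12)
      y <- scores %*% c(1, -2, 1.5) + rnorm(60, 0, 0.4)
    })
    sel <- select_nlv(x, as.vector(y), max_nlv = 8, seed = s)
    hits <- hits + (sel$best == 3)
  }
  expect_gt(hits, 7) # modal choice is the true dimension
  # noiseless one-factor data needs exactly one latent variable
  withr::with_seed(77, {
    t1 <- rnorm(30)
    x1 <- t1 %o% c(1, 2, 3)
  })
  expect_equal(select_nlv(x1, 3 * t1, max_nlv = 5, seed = 1)$best, 1)
})

test_that("select_nlv is deterministic and reports a full curve", {
  withr::with_seed(40, {
    x <- matrix(rnorm(30 * 8), 30, 8)
    y <- rnorm(30)
  })
  a <- select_nlv(x, y, max_nlv = 6, seed = 9)
  b <- select_nlv(x, y, max_nlv = 6, seed = 9)
  expect_identical(a, b)
  expect_equal(a$curve$n_lv, 1:6)
})

test_that("SVR matches an explicit dual QP solution on a small problem", {
  skip_if_not_installed("kernlab")
  withr::with_seed(50, {
    x <- matrix(c(-2, -1, 0, 1, 2), 5, 1)
    y <- c(0.1, 0.8, 1.9, 3.2, 3.9)
  })
  gamma <- 0.5
  cost <- 10
  eps <- 0.1
  fit <- svr_fit(x, y, gamma, cost, eps)
  # replicate the model's internal standardisation, then solve the dual QP
  xs <- csacal:::apply_scaling(x, fit$x_center, fit$x_scale)
  ys <- (y - fit$y_center) / fit$y_scale
  K <- rbf_kernel(xs, xs, gamma)
  qp <- oracle_svr_qp(K, ys, cost, eps)
  pred_qp <- (as.vector(K %*% qp$coef) + qp$b) * fit$y_scale + fit$y_center
  expect_equal(predict(fit, x), pred_qp, tolerance = 1e-4)
})

test_that("SVR limits behave: interpolation at large cost, mean at tiny cost", {
  withr::with_seed(51, {
    x <- matrix(rnorm(20 * 2), 20, 2)
    y <- x[, 1]^2 + rnorm(20, 0, 0.01)
  })
  big <- svr_fit(x, y, gamma = 0.5, cost = 1e4, epsilon = 0.01)
  expect_lt(max(abs(predict(big, x) - y)), 0.05 * sd(y) + 0.02)
  # fully regularized limit: the fit collapses to a constant near the
  # response centre (for symmetric responses that constant is the mean)
  withr::with_seed(54, {
    ys <- x[, 1] + rnorm(20, 0, 0.2)
  })
  tiny <- svr_fit(x, ys, gamma = 0.5, cost = 1e-6)
  expect_lt(diff(range(predict(tiny, x))), 0.01 * sd(ys))
  expect_lt(max(abs(predict(tiny, x) - mean(ys))), 0.25 * sd(ys))
  expect_error(svr_fit(x, y, gamma = -1, cost = 1), "must be > 0")
})

test_that("grid search is exhaustive, deterministic, and recovers kernel scale", {
  withr::with_seed(52, {
    x <- matrix(runif(50, -2, 2), 50, 1)
    y <- sin(2 * x[, 1]) + rnorm(50, 0, 0.05)
  })
  gs <- grid_search_svr(x, y, g_grid = 2^(-4:4), c_grid = 2^(-2:6), seed = 4)
  expect_equal(nrow(gs$grid), 9 * 9)
  expect_identical(
    gs$grid,
    grid_search_svr(x, y, g_grid = 2^(-4:4), c_grid = 2^(-2:6), seed = 4)$grid
  )
  expect_equal(gs$best_rmsecv, min(gs$grid$rmsecv))
  # the sin(2x) scale needs a mid-range gamma, not the grid edges
  expect_true(gs$best_gamma %in% 2^(-2:4))

  one <- grid_search_svr(x, y, g_grid = 1, c_grid = 2, seed = 4)
  expect_equal(c(one$best_gamma, one$best_cost), c(1, 2))
  expect_error(grid_search_svr(x, y, g_grid = numeric(), c_grid = 1), "non-empty")
})

test_that("adding a constant column does not change SVR predictions", {
  withr::with_seed(53, {
    x <- matrix(rnorm(30 * 3), 30, 3)
    y <- x[, 1] - x[, 2]^2 + rnorm(30, 0.1)
  })
  f1 <- svr_fit(x, y, 0.3, 4)
  f2 <- svr_fit(cbind(x, 5), y, 0.3, 4)
  expect_equal(predict(f1, x), predict(f2, cbind(x, 5)), tolerance = 1e-10)
})
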