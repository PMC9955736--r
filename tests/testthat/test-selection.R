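test_that("retained fractions reproduce the reporting convention", {
  expect_equal(retained_fraction_report(13, 90), 14.44)
  expect_equal(retained_fraction_report(30, 90), 33.33)
  expect_equal(retained_fraction_report(18, 90), 20)
  expect_equal(retained_fraction_report(0, 90), 0)
  expect_error(retained_fraction_report(5, 0), "positive")
  expect_error(retained_fraction_report(10, 5), "exceeds")
})

test_that("UVE retains a column that exactly equals the response", {
  withr::with_seed(70, {
    x <- matrix(rnorm(30 * 8), 30, 8)
    y <- rnorm(30)
  })
  x[, 3] <- y
  sel <- suppressWarnings(uve_select(x, y, n_lv = 2, seed = 1))
  expect_true(3 %in% sel$selected)
  expect_true(all(sel$selected %in% 1:8))
})

test_that("UVE null retention tracks one minus the cutoff quantile", {
  # pure-noise data: real and artificial stabilities share a distribution,
  # so about 1% of real variables survive a 0.99 cutoff
  fracs <- vapply(1:30, function(s) {
    withr::with_seed(700 + s, {
      x <- matrix(rnorm(25 * 40), 25, 40)
      y <- rnorm(25)
    })
    sel <- uve_select(x, y, n_lv = 3, seed = s)
    length(sel$selected) / 40
  }, 0)
  # binomial-ish band around 0.01
  expect_lt(mean(fracs), 0.05)
  expect_gte(mean(fracs), 0)
})

test_that("UVE output is reproducible and carries the cutoff", {
  withr::with_seed(71, {
    x <- matrix(rnorm(25 * 10), 25, 10)
    y <- x[, 2] + rnorm(25, 0, 0.1)
  })
  a <- uve_select(x, y, seed = 5)
  b <- uve_select(x, y, seed = 5)
  expect_identical(a$selected, b$selected)
  expect_identical(a$scores, b$scores)
  expect_true(is.finite(a$cutoff))
  expect_equal(a$retained_fraction, retained_fraction_report(length(a$selected), 10))
})

test_that("the CARS retention schedule declines from p to 2", {
  counts <- csacal:::cars_edf_counts(90, 25)
  expect_equal(counts[1], 90)
  expect_equal(counts[25], 2)
  expect_true(all(diff(counts) <= 0))
  # closed form: ceiling(a * exp(-k i) * p) clipped to [2, p]
  k <- log(90 / 2) / 24
  ratio <- exp(k) * exp(-k * (1:25))
  expect_equal(counts, pmin(90, pmax(2L, ceiling(ratio * 90 - 1e-9))))
  # endpoints are exact by construction
  expect_equal(ratio[1] * 90, 90, tolerance = 1e-12)
  expect_equal(ratio[25] * 90, 2, tolerance = 1e-12)
})

test_that("CARS keeps subsets inside the input set and ends near two", {
  withr::with_seed(72, {
    x <- matrix(rnorm(30 * 12), 30, 12)
    y <- x[, 1] + 0.5 * x[, 2] + rnorm(30, 0, 0.2)
  })
  sel <- cars_select(x, y, n_mc_runs = 10, seed = 2)
  expect_true(all(sel$selected %in% 1:12))
  expect_true(all(sel$history$n_retained >= 2))
  expect_true(all(diff(sel$history$n_retained) <= 0))
  expect_lte(sel$history$n_retained[10], sel$history$edf_count[10])
  expect_identical(sel$selected, cars_select(x, y, n_mc_runs = 10, seed = 2)$selected)

  # two-variable input: both runs' subsets stay within the pair
  p2 <- cars_select(matrix(rnorm(40), 20, 2), rnorm(20), n_mc_runs = 5, seed = 3)
  expect_true(all(p2$selected %in% 1:2))
})

test_that("CARS final subset beats or matches the full model by RMSECV", {
  withr::with_seed(73, {
    x <- matrix(rnorm(40 * 20), 40, 20)
    y <- x[, 5] - x[, 12] + rnorm(40, 0, 0.3)
  })
  sel <- cars_select(x, y, seed = 4)
  folds <- kfold_indices(40, 5, csacal:::derive_seed(4, 1))
  full_cv <- csacal:::rmsecv(x, y, folds, function(xt, yt) {
    pls_fit(xt, yt, n_lv = min(5, ncol(xt)))
  })
  expect_lte(min(sel$history$rmsecv), full_cv)
})

test_that("random frog probabilities are well-formed and reproducible", {
  withr::with_seed(74, {
    x <- matrix(rnorm(25 * 15), 25, 15)
    y <- x[, 4] + rnorm(25, 0, 0.2)
  })
  a <- random_frog_select(x, y, n_iterations = 10, top_k = 5, seed = 6)
  b <- random_frog_select(x, y, n_iterations = 10, top_k = 5, seed = 6)
  expect_identical(a$scores, b$scores)
  expect_true(all(a$scores$score >= 0 & a$scores$score <= 1))
  expect_length(a$selected, 5)
  expect_error(random_frog_select(x, y, q_init = 50), "1..p")
})

test_that("a variable present in every accepted subset scores exactly one", {
  withr::with_seed(75, {
    x <- matrix(rnorm(30 * 6), 30, 6)
    y <- 3 * x[, 2] + rnorm(30, 0, 0.05)
  })
  # start from the full variable set so the dominant variable is present
  # from iteration one; it then tops every |beta| ranking and never leaves
  sel <- random_frog_select(x, y,
    n_iterations = 100, q_init = 6, top_k = 2, seed = 7
  )
  expect_equal(max(sel$scores$score), 1)
  expect_equal(sel$scores$score[2], 1)
  expect_true(all(sel$scores$score >= 0 & sel$scores$score <= 1))
})

test_that("selection results serialize to JSON with scores CSV", {
  withr::with_seed(76, {
    x <- matrix(rnorm(20 * 6), 20, 6)
    y <- x[, 1] + rnorm(20, 0, 0.1)
  })
  sel <- uve_select(x, y, seed = 2)
  path <- file.path(withr::local_tempdir(), "sel.json")
  write_selection(sel, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$algorithm, "UVE")
  expect_equal(back$selected_indices, sel$selected)
  expect_true(file.exists(sub("\\.json$", "_scores.csv", path)))
})
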