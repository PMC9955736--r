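uniform_image <- function(rgb, h = 60, w = 60) {
  img <- array(0, c(h, w, 3))
  for (ch in 1:3) img[, , ch] <- rgb[ch]
  img
}

test_that("spot masks select the nearest pixels with row-major tie-break", {
  layout <- array_layout(data.frame(x = 30, y = 30), 1, 1, mask_pixels = 5)
  mask <- build_spot_mask(layout, 1, c(60, 60))
  # centre plus its four axial neighbours
  expect_setequal(
    paste(mask[, "row"], mask[, "col"]),
    c("30 30", "29 30", "31 30", "30 29", "30 31")
  )

  layout800 <- array_layout(data.frame(x = 30, y = 30), 1, 1, mask_pixels = 800)
  m800 <- build_spot_mask(layout800, 1, c(120, 120))
  expect_equal(nrow(m800), 800)
  expect_equal(anyDuplicated(paste(m800[, 1], m800[, 2])), 0L)

  # brute-force oracle over the whole image
  layout37 <- array_layout(data.frame(x = 14, y = 9), 1, 1, mask_pixels = 37)
  got <- build_spot_mask(layout37, 1, c(25, 30))
  ref <- oracle_spot_mask(14, 9, 25, 30, 37)
  expect_equal(got[order(got[, 1], got[, 2]), ], ref[order(ref[, 1], ref[, 2]), ])
})

test_that("default-size masks are 4-connected", {
  layout <- array_layout(data.frame(x = 40, y = 40), 1, 1, mask_pixels = 800)
  mask <- build_spot_mask(layout, 1, c(90, 90))
  keys <- paste(mask[, "row"], mask[, "col"])
  # flood fill from the first pixel through axial neighbours
  seen <- keys[1]
  frontier <- keys[1]
  while (length(frontier) > 0) {
    parts <- do.call(rbind, strsplit(frontier, " "))
    r <- as.integer(parts[, 1])
    cc <- as.integer(parts[, 2])
    nb <- unique(c(
      paste(r + 1, cc), paste(r - 1, cc), paste(r, cc + 1), paste(r, cc - 1)
    ))
    frontier <- setdiff(intersect(nb, keys), seen)
    seen <- union(seen, frontier)
  }
  expect_setequal(seen, keys)
})

test_that("mask bounds errors are raised", {
  layout <- array_layout(data.frame(x = 200, y = 10), 1, 1, mask_pixels = 10)
  expect_error(build_spot_mask(layout, 1, c(50, 50)), "outside")
  big <- array_layout(data.frame(x = 5, y = 5), 1, 1, mask_pixels = 1e5)
  expect_error(build_spot_mask(big, 1, c(10, 10)), "exceed")
})

test_that("mean spot colour equals brute-force accumulation", {
  withr::with_seed(4, {
    img <- array(runif(10 * 10 * 3, 0, 255), c(10, 10, 3))
  })
  layout <- array_layout(data.frame(x = 5, y = 5), 1, 1, mask_pixels = 20)
  mask <- build_spot_mask(layout, 1, c(10, 10))
  got <- mean_spot_color(img, mask)
  acc <- c(0, 0, 0)
  for (i in seq_len(nrow(mask))) {
    acc <- acc + img[mask[i, 1], mask[i, 2], ]
  }
  expect_equal(unname(got), acc / nrow(mask), tolerance = 1e-12)
  expect_equal(
    unname(mean_spot_color(uniform_image(c(120, 30, 200)), mask)),
    c(120, 30, 200)
  )
})

test_that("fingerprints difference colours after conversion, with RGB euclid", {
  fp0 <- compute_fingerprint(c(10, 20, 30), c(10, 20, 30))
  expect_equal(unname(fp0), rep(0, 10))

  fp <- compute_fingerprint(c(100, 100, 100), c(103, 104, 100))
  expect_equal(unname(fp[c("dR", "dG", "dB", "euclid")]), c(3, 4, 0, 5))

  a <- c(40, 180, 90)
  b <- c(200, 60, 130)
  fp_ab <- compute_fingerprint(a, b)
  expect_equal(
    unname(fp_ab[4:6]), unname(rgb_to_hsv(b) - rgb_to_hsv(a)),
    tolerance = 1e-12
  )
  expect_equal(
    unname(fp_ab[7:9]), unname(rgb_to_lab(b) - rgb_to_lab(a)),
    tolerance = 1e-12
  )
  # antisymmetry of signed deltas; symmetry of the magnitude
  fp_ba <- compute_fingerprint(b, a)
  expect_equal(unname(fp_ab[1:9]), -unname(fp_ba[1:9]), tolerance = 1e-12)
  expect_equal(fp_ab[["euclid"]], fp_ba[["euclid"]])
})

test_that("feature extraction yields 90 ordered features on a 3x3 array", {
  layout <- grid_layout(150, 150)
  deltas <- matrix(0, 9, 3)
  deltas[5, ] <- c(40, -20, 10)
  pair <- render_image_pair(deltas, layout, image_shape = c(150, 150))
  fv <- extract_feature_vector(pair$before, pair$after, layout)
  expect_length(fv, 90)
  expect_equal(names(fv)[1:2], c("spot1_dR", "spot1_dG"))
  expect_equal(names(fv)[90], "spot9_euclid")
  nz <- which(fv != 0)
  expect_true(all(nz %in% 41:50)) # spot 5 block only
  expect_equal(unname(fv[41:43]), c(40, -20, 10))

  same <- extract_feature_vector(pair$before, pair$before, layout)
  expect_equal(unname(same), rep(0, 90))
  expect_error(
    extract_feature_vector(pair$before, pair$after[1:100, , ], layout),
    "identical dimensions"
  )
})

test_that("extraction is invariant to translating image and layout together", {
  layout <- grid_layout(120, 120, mask_pixels = 200)
  withr::with_seed(9, {
    deltas <- matrix(round(runif(27, -30, 30)), 9, 3)
  })
  pair <- render_image_pair(deltas, layout, image_shape = c(120, 120))
  fv1 <- extract_feature_vector(pair$before, pair$after, layout)

  pad <- function(img, dr, dc) {
    out <- array(230, c(dim(img)[1] + dr, dim(img)[2] + dc, 3))
    out[(dr + 1):(dr + dim(img)[1]), (dc + 1):(dc + dim(img)[2]), ] <- img
    out
  }
  shifted <- array_layout(
    data.frame(
      x = layout$spot_centers$x + 7,
      y = layout$spot_centers$y + 11
    ),
    mask_pixels = 200
  )
  fv2 <- extract_feature_vector(
    pad(pair$before, 11, 7), pad(pair$after, 11, 7), shifted
  )
  expect_equal(fv1, fv2, tolerance = 1e-12)
})

test_that("feature tables assemble, round-trip via CSV, and handle 0 samples", {
  layout <- grid_layout(90, 90, mask_pixels = 50)
  empty <- assemble_feature_table(list(), layout)
  expect_equal(nrow(empty), 0)
  expect_equal(ncol(empty), 93) # id, day, 90 features, tvbn

  withr::with_seed(21, {
    samples <- lapply(1:5, function(i) {
      deltas <- matrix(round(runif(27, -25, 25)), 9, 3)
      pair <- render_image_pair(deltas, layout, image_shape = c(90, 90))
      list(
        before = pair$before, after = pair$after,
        sample_id = paste0("S", i), storage_day = i, tvbn = 10 + i
      )
    })
  })
  tbl <- assemble_feature_table(samples, layout)
  expect_equal(dim(tbl), c(5L, 93L))
  expect_equal(tbl$sample_id, paste0("S", 1:5))

  path <- withr::local_tempfile(fileext = ".csv")
  write_feature_table(tbl, path)
  back <- read_feature_table(path)
  expect_equal(
    as.matrix(back[3:92]), as.matrix(tbl[3:92]),
    tolerance = 1e-12, ignore_attr = TRUE
  )
})

test_that("rendered image pairs survive PNG write/read round trips", {
  layout <- grid_layout(90, 90, mask_pixels = 50)
  deltas <- matrix(0, 9, 3)
  deltas[2, ] <- c(25, 0, -15) # integer deltas stay exact in 8-bit PNG
  pair <- render_image_pair(deltas, layout, image_shape = c(90, 90))
  pb <- withr::local_tempfile(fileext = ".png")
  pa <- withr::local_tempfile(fileext = ".png")
  write_scan(pair$before, pb)
  write_scan(pair$after, pa)
  fv <- extract_feature_vector(read_scan(pb), read_scan(pa), layout)
  expect_equal(unname(fv[11:13]), c(25, 0, -15), tolerance = 1e-6)
})
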