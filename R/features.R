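#' Describe a dye-spot array layout
#'
#' A CSA scan holds a regular grid of dye spots (3 x 3 = nine dyes by
#' default). The layout records the spot centres in pixel coordinates and
#' how many pixels around each centre are averaged into that spot's colour
#' (800 by default, realised as the 800 pixels nearest the centre).
#'
#' @param spot_centers Data frame or matrix with columns `x`, `y`: spot
#'   centres in pixel coordinates (x = column, y = row, 1-based).
#' @param n_rows,n_cols Grid dimensions; their product must equal the number
#'   of centres.
#' @param mask_pixels Pixels averaged per spot (>= 1).
#' @return An object of class `csa_layout`.
#' @seealso [grid_layout()] for an evenly spaced default grid.
#' @export
array_layout <- function(spot_centers, n_rows = 3, n_cols = 3,
                         mask_pixels = 800) {
  ctr <- as.data.frame(spot_centers)
  if (!all(c("x", "y") %in% names(ctr))) {
    names(ctr) <- c("x", "y")[seq_len(ncol(ctr))]
  }
  if (nrow(ctr) != n_rows * n_cols) {
    abort(sprintf(
      "Layout has %d centres but n_rows * n_cols = %d.",
      nrow(ctr), n_rows * n_cols
    ))
  }
  if (mask_pixels < 1) abort("`mask_pixels` must be >= 1.")
  structure(
    list(
      n_rows = as.integer(n_rows),
      n_cols = as.integer(n_cols),
      spot_centers = tibble::as_tibble(ctr[c("x", "y")]),
      mask_pixels = as.integer(mask_pixels)
    ),
    class = "csa_layout"
  )
}

#' Evenly spaced spot grid for a given image size
#'
#' @param width,height Image size in pixels.
#' @inheritParams array_layout
#' @return A `csa_layout`.
#' @export
grid_layout <- function(width, height, n_rows = 3, n_cols = 3,
                        mask_pixels = 800) {
  xs <- round(width * (seq_len(n_cols) - 0.5) / n_cols)
  ys <- round(height * (seq_len(n_rows) - 0.5) / n_rows)
  ctr <- expand.grid(x = xs, y = ys)[, c("x", "y")]
  array_layout(ctr, n_rows, n_cols, mask_pixels)
}

#' @export
print.csa_layout <- function(x, ...) {
  cat(sprintf(
    "<csa_layout> %d x %d spots, %d pixels per spot mask\n",
    x$n_rows, x$n_cols, x$mask_pixels
  ))
  invisible(x)
}

n_spots <- function(layout) layout$n_rows * layout$n_cols

#' Pixels averaged for one dye spot
#'
#' Selects exactly `mask_pixels` pixels, the ones nearest the spot centre in
#' Euclidean pixel distance; distance ties are broken in row-major pixel
#' order so the mask is deterministic.
#'
#' @param layout A [array_layout()].
#' @param spot_index Spot number (1-based, row-major over the grid).
#' @param image_shape Integer `c(height, width)` of the image the mask will
#'   be applied to.
#' @return Integer matrix with columns `row`, `col`, one row per mask pixel.
#' @export
build_spot_mask <- function(layout, spot_index, image_shape) {
  stopifnot(inherits(layout, "csa_layout"))
  if (spot_index < 1 || spot_index > n_spots(layout)) {
    abort("`spot_index` out of range for layout.")
  }
  h <- image_shape[1]
  w <- image_shape[2]
  cx <- layout$spot_centers$x[spot_index]
  cy <- layout$spot_centers$y[spot_index]
  if (cx < 1 || cx > w || cy < 1 || cy > h) {
    abort(sprintf("Spot centre (%g, %g) lies outside a %dx%d image.", cx, cy, h, w))
  }
  m <- layout$mask_pixels
  if (m > h * w) abort("Mask would exceed the image pixel count.")

  # Grow a window around the centre until the m-th nearest pixel provably
  # lies inside it (any pixel outside a half-width-r window is > r away).
  r <- ceiling(sqrt(m))
  repeat {
    rows <- max(1, floor(cy - r)):min(h, ceiling(cy + r))
    cols <- max(1, floor(cx - r)):min(w, ceiling(cx + r))
    px <- expand.grid(col = cols, row = rows) # row-major enumeration
    d2 <- (px$col - cx)^2 + (px$row - cy)^2
    if (nrow(px) >= m) {
      ord <- order(d2, (px$row - 1) * w + px$col)
      kth <- sqrt(d2[ord[m]])
      window_full <- (length(rows) == h && length(cols) == w)
      if (kth <= r || window_full) {
        sel <- ord[seq_len(m)]
        return(cbind(row = as.integer(px$row[sel]), col = as.integer(px$col[sel])))
      }
    } else if (length(rows) == h && length(cols) == w) {
      abort("Mask would exceed the image pixel count.")
    }
    r <- r * 2
  }
}

#' Mean colour over a spot mask
#'
#' @param image Numeric array `height x width x 3`, channel values in
#'   `[0, 255]`.
#' @param mask Pixel matrix from [build_spot_mask()].
#' @return Named numeric vector `c(R, G, B)` of unrounded channel means.
#' @export
mean_spot_color <- function(image, mask) {
  if (is.null(dim(mask)) || nrow(mask) == 0) abort("Empty spot mask.")
  d <- dim(image)
  if (any(mask[, "row"] > d[1]) || any(mask[, "col"] > d[2]) || any(mask < 1)) {
    abort("Mask pixels fall outside the image.")
  }
  idx_r <- cbind(mask, 1L)
  idx_g <- cbind(mask, 2L)
  idx_b <- cbind(mask, 3L)
  c(R = mean(image[idx_r]), G = mean(image[idx_g]), B = mean(image[idx_b]))
}

fingerprint_names <- c(
  "dR", "dG", "dB", "dH", "dS", "dV", "dL", "dA", "dBlab", "euclid"
)

#' Colour-difference fingerprint of one dye spot
#'
#' Ten features per spot: signed after-minus-before deltas in RGB, HSV and
#' CIELAB (each colour converted before differencing), plus the Euclidean
#' distance of the RGB delta. The CIELAB a/b channels are named `dA` and
#' `dBlab` to avoid the clash with the blue RGB channel.
#'
#' @param before,after Named RGB vectors (channel means in `[0, 255]`).
#' @return Named numeric vector of length 10.
#' @export
compute_fingerprint <- function(before, after) {
  check_rgb(before)
  check_rgb(after)
  d_rgb <- unname(after - before)
  d_hsv <- unname(rgb_to_hsv(after) - rgb_to_hsv(before))
  d_lab <- unname(rgb_to_lab(after) - rgb_to_lab(before))
  out <- c(d_rgb, d_hsv, d_lab, sqrt(sum(d_rgb^2)))
  names(out) <- fingerprint_names
  out
}

#' Feature names for a full array fingerprint
#'
#' @param layout A `csa_layout` (default 3 x 3).
#' @return Character vector `spot1_dR` ... `spot<n>_euclid`.
#' @export
csa_feature_names <- function(layout = grid_layout(300, 300)) {
  as.vector(t(outer(
    paste0("spot", seq_len(n_spots(layout))),
    fingerprint_names, paste,
    sep = "_"
  )))
}

#' Extract the full colour fingerprint of a before/after scan pair
#'
#' @param before,after Numeric arrays `height x width x 3` in `[0, 255]`,
#'   same shape.
#' @param layout A [array_layout()] valid for that shape.
#' @return Named numeric vector of length `n_spots * 10`, ordered spot-major
#'   then (dR, dG, dB, dH, dS, dV, dL, dA, dBlab, euclid).
#' @export
extract_feature_vector <- function(before, after, layout) {
  if (!identical(dim(before), dim(after))) {
    abort("`before` and `after` images must have identical dimensions.")
  }
  shape <- dim(before)[1:2]
  out <- unlist(lapply(seq_len(n_spots(layout)), function(i) {
    mask <- build_spot_mask(layout, i, shape)
    compute_fingerprint(
      mean_spot_color(before, mask),
      mean_spot_color(after, mask)
    )
  }))
  names(out) <- csa_feature_names(layout)
  out
}

#' Assemble a feature table from scan pairs
#'
#' @param samples List of samples; each a list with elements `before` and
#'   `after` (image arrays), `sample_id`, `storage_day`, and optionally
#'   `tvbn` (reference TVB-N, mg/100 g).
#' @param layout A [array_layout()].
#' @return Tibble with columns `sample_id`, `storage_day`, one column per
#'   feature, and `tvbn` (NA where no reference was supplied). Row order
#'   follows the input.
#' @export
assemble_feature_table <- function(samples, layout) {
  fnames <- csa_feature_names(layout)
  if (length(samples) == 0) {
    empty <- c(
      list(sample_id = character(), storage_day = numeric()),
      stats::setNames(rep(list(numeric()), length(fnames)), fnames),
      list(tvbn = numeric())
    )
    return(tibble::as_tibble(empty))
  }
  shapes <- vapply(samples, function(s) paste(dim(s$before), collapse = "x"), "")
  if (length(unique(shapes)) != 1) {
    abort("All sample images must share one size.")
  }
  rows <- purrr::map(samples, function(s) {
    fv <- extract_feature_vector(s$before, s$after, layout)
    tibble::as_tibble_row(c(
      list(
        sample_id = as.character(s$sample_id),
        storage_day = as.numeric(s$storage_day)
      ),
      as.list(fv),
      list(tvbn = as.numeric(s$tvbn %||% NA_real_))
    ))
  })
  dplyr::bind_rows(rows)
}

#' Read an 8-bit RGB scan (PNG or TIFF) as a 0-255 array
#'
#' @param path Image file path.
#' @return Numeric array `height x width x 3` with values in `[0, 255]`.
#' @export
read_scan <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    abort(sprintf("Unsupported image format '%s' (PNG/TIFF only).", ext))
  )
  if (length(dim(img)) == 2) img <- array(rep(img, 3), c(dim(img), 3))
  img[, , 1:3, drop = FALSE] * 255
}

#' Write a 0-255 image array as PNG
#'
#' @param image Numeric array `height x width x 3`, values in `[0, 255]`.
#' @param path Output path.
#' @export
write_scan <- function(image, path) {
  png::writePNG(pmin(pmax(image / 255, 0), 1), path)
  invisible(path)
}

#' Write / read a feature table as CSV
#'
#' Values round-trip at full double precision.
#'
#' @param data Feature table tibble.
#' @param path CSV path.
#' @return `read_feature_table()` returns the tibble; the writer returns the
#'   path invisibly.
#' @export
write_feature_table <- function(data, path) {
  readr::write_csv(data, path)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}
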