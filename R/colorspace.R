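#' Convert an RGB colour to HSV
#'
#' Standard hexcone conversion with all three channels scaled to `[0, 1]`
#' (hue included, so no single channel dominates distance-based steps
#' downstream). Achromatic colours have saturation 0 and hue defined as 0.
#'
#' @param rgb Numeric vector of length 3, channel intensities in `[0, 255]`.
#' @return Named numeric vector `c(H, S, V)`, each in `[0, 1]`.
#' @examples
#' rgb_to_hsv(c(255, 0, 0)) # pure red: H = 0, S = 1, V = 1
#' @export
rgb_to_hsv <- function(rgb) {
  check_rgb(rgb)
  v <- rgb / 255
  mx <- max(v)
  mn <- min(v)
  d <- mx - mn
  h <- if (d == 0) {
    0
  } else if (mx == v[1]) {
    (((v[2] - v[3]) / d) %% 6) / 6
  } else if (mx == v[2]) {
    ((v[3] - v[1]) / d + 2) / 6
  } else {
    ((v[1] - v[2]) / d + 4) / 6
  }
  s <- if (mx == 0) 0 else d / mx
  c(H = h, S = s, V = mx)
}

# sRGB linear-light transfer (IEC 61966-2-1).
srgb_linearize <- function(v) {
  ifelse(v <= 0.04045, v / 12.92, ((v + 0.055) / 1.055)^2.4)
}

# sRGB (D65) to CIE XYZ matrix, derived at full precision from the primary
# chromaticities (R 0.64/0.33, G 0.30/0.60, B 0.15/0.06) and the D65 white
# point 0.3127/0.3290, with Y normalised to 1 for white. Published tables
# round this to 7 digits (0.4124564, ...).
.srgb_constants <- local({
  xyz_col <- function(x, y) c(x / y, 1, (1 - x - y) / y)
  P <- cbind(xyz_col(0.64, 0.33), xyz_col(0.30, 0.60), xyz_col(0.15, 0.06))
  w <- xyz_col(0.3127, 0.3290)
  list(M = P %*% diag(solve(P, w)), white = w)
})
.srgb_to_xyz <- .srgb_constants$M
.d65_white <- .srgb_constants$white

#' Convert an RGB colour to CIELAB
#'
#' sRGB is linearised with the standard piecewise transfer function, mapped
#' to CIE XYZ (D65 white point), then to CIELAB via the cube-root/linear
#' piecewise function. L lies in `[0, 100]` on its native scale.
#'
#' @inheritParams rgb_to_hsv
#' @return Named numeric vector `c(L, a, b)`.
#' @examples
#' rgb_to_lab(c(255, 255, 255)) # reference white: L = 100, a = b = 0
#' @export
rgb_to_lab <- function(rgb) {
  check_rgb(rgb)
  xyz <- as.vector(.srgb_to_xyz %*% srgb_linearize(rgb / 255))
  t <- xyz / .d65_white
  delta <- 6 / 29
  ft <- ifelse(t > delta^3, t^(1 / 3), t / (3 * delta^2) + 4 / 29)
  c(
    L = 116 * ft[2] - 16,
    a = 500 * (ft[1] - ft[2]),
    b = 200 * (ft[2] - ft[3])
  )
}

check_rgb <- function(rgb) {
  if (length(rgb) != 3 || !is.numeric(rgb) || anyNA(rgb)) {
    abort("An RGB colour must be 3 finite numeric values.")
  }
  if (any(rgb < 0) || any(rgb > 255)) {
    abort("RGB channels must lie in [0, 255].")
  }
  invisible(rgb)
}
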