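#' @importFrom rlang .data abort warn %||%
#' @importFrom stats cor predict quantile rnorm runif sd qnorm
#' @importFrom utils head
NULL

# Round half away from zero (base round() is banker's rounding).
round_half_up <- function(x, digits = 0) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

# Column autoscaling (center + unit variance); zero-variance columns are
# centered only, so they carry no weight downstream instead of producing NaN.
autoscale <- function(x) {
  x <- as.matrix(x)
  ctr <- colMeans(x)
  scl <- apply(x, 2, sd)
  scl[!is.finite(scl) | scl < .Machine$double.eps] <- 1
  list(
    x = sweep(sweep(x, 2, ctr, "-"), 2, scl, "/"),
    center = ctr,
    scale = scl
  )
}

apply_scaling <- function(x, center, scale) {
  x <- as.matrix(x)
  sweep(sweep(x, 2, center, "-"), 2, scale, "/")
}

rmse <- function(obs, pred) sqrt(mean((obs - pred)^2))

# Extract the numeric feature matrix from a feature table (tibble with
# metadata columns) or pass a plain matrix through.
feature_matrix <- function(data) {
  if (is.matrix(data)) {
    return(data)
  }
  meta <- intersect(c("sample_id", "storage_day", "tvbn"), names(data))
  m <- as.matrix(data[setdiff(names(data), meta)])
  storage.mode(m) <- "double"
  m
}

check_xy <- function(x, y) {
  x <- as.matrix(x)
  if (!is.numeric(x)) abort("`x` must be a numeric matrix.")
  if (nrow(x) != length(y)) {
    abort(sprintf(
      "`x` has %d rows but `y` has length %d.", nrow(x), length(y)
    ))
  }
  if (anyNA(x) || anyNA(y)) abort("`x` and `y` must not contain missing values.")
  x
}

# Deterministic derived seeds for pipeline stages; kept far below 2^31.
derive_seed <- function(seed, offset) {
  (as.integer(seed) %% 1000000L) * 1000L + as.integer(offset)
}
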