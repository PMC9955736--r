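#' Configuration for the synthetic CSA study generator
#'
#' Emulates the structure of the chicken-breast storage study: samples drawn
#' over an 11-day refrigerated storage at six time points, a reference TVB-N
#' value rising monotonically with storage day, and a 90-variable colour
#' fingerprint in which a small known subset responds (by default
#' nonlinearly, with sigmoid saturation — the standard dye-response
#' assumption) to TVB-N while the remaining variables are noise.
#'
#' @param n_samples Total samples (default 80).
#' @param storage_days Storage time points in days (default 1, 3, ..., 11);
#'   samples are assigned by ceiling division, earliest days first.
#' @param tvbn_start,tvbn_end Mean reference TVB-N (mg/100 g) at the first
#'   and last storage day (defaults 8 and 45; a typical fresh-to-spoiled
#'   span for chilled poultry).
#' @param tvbn_noise_sd Gaussian sd of per-sample TVB-N around its day mean,
#'   mg/100 g (default 1.0); draws are clipped at 0.
#' @param n_variables Fingerprint width (default 90).
#' @param informative_indices Indices of the responding variables (default
#'   10 indices spread across the spot blocks: `seq(5, 86, by = 9)`).
#' @param response_kind `"sigmoid"` (default), `"linear"` or `"quadratic"`.
#' @param feature_noise_sd Gaussian noise sd added to informative columns,
#'   in response units (default 0.1 against a response amplitude of 1).
#' @param seed Integer seed; the whole dataset is a deterministic function
#'   of the configuration.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_samples = 80,
                             storage_days = c(1, 3, 5, 7, 9, 11),
                             tvbn_start = 8, tvbn_end = 45,
                             tvbn_noise_sd = 1.0,
                             n_variables = 90,
                             informative_indices = seq(5, 86, by = 9),
                             response_kind = c("sigmoid", "linear", "quadratic"),
                             feature_noise_sd = 0.1,
                             seed = 1) {
  response_kind <- match.arg(response_kind)
  if (tvbn_end <= tvbn_start) abort("`tvbn_end` must exceed `tvbn_start`.")
  if (tvbn_noise_sd < 0 || feature_noise_sd < 0) abort("Noise sds must be >= 0.")
  informative_indices <- as.integer(informative_indices)
  if (any(informative_indices < 1) || any(informative_indices > n_variables)) {
    abort("`informative_indices` must lie within 1..n_variables.")
  }
  if (anyDuplicated(informative_indices)) {
    abort("`informative_indices` must be unique.")
  }
  structure(
    list(
      n_samples = as.integer(n_samples),
      storage_days = as.numeric(storage_days),
      tvbn_start = tvbn_start, tvbn_end = tvbn_end,
      tvbn_noise_sd = tvbn_noise_sd,
      n_variables = as.integer(n_variables),
      informative_indices = informative_indices,
      response_kind = response_kind,
      feature_noise_sd = feature_noise_sd,
      seed = as.integer(seed)
    ),
    class = "synthetic_config"
  )
}

# Assign samples to storage days: ceiling shares, earliest days first
# (80 samples over 6 days -> 14,14,14,14,14,10).
assign_days <- function(config) {
  days <- config$storage_days
  n <- config$n_samples
  per <- ceiling(n / length(days))
  rep(days, times = pmax(0, pmin(per, n - per * (seq_along(days) - 1))))
}

day_means <- function(config, day) {
  d1 <- min(config$storage_days)
  dN <- max(config$storage_days)
  config$tvbn_start +
    (config$tvbn_end - config$tvbn_start) * (day - d1) / (dN - d1)
}

generate_tvbn_impl <- function(config) {
  day <- assign_days(config)
  mu <- day_means(config, day)
  y <- pmax(0, mu + rnorm(length(mu), 0, config$tvbn_noise_sd))
  tibble::tibble(
    sample_id = sprintf("S%03d", seq_along(y)),
    storage_day = day,
    tvbn = y
  )
}

#' Generate a synthetic TVB-N storage trajectory
#'
#' Per-day means interpolate linearly from `tvbn_start` to `tvbn_end` over
#' the storage days; Gaussian per-sample noise is clipped at 0 (TVB-N is a
#' concentration).
#'
#' @param config A [synthetic_config()].
#' @return Tibble with `sample_id`, `storage_day`, `tvbn`.
#' @export
generate_tvbn_profile <- function(config) {
  withr::with_seed(config$seed, generate_tvbn_impl(config))
}

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Generate a synthetic feature table with known ground truth
#'
#' Informative columns are a (by default sigmoid-saturating) function of the
#' sample's TVB-N plus Gaussian noise; all other columns are pure standard
#' Gaussian noise. Per-variable response parameters (sign, midpoint, slope)
#' are drawn once from the seeded RNG and reported in the ground truth.
#'
#' @param config A [synthetic_config()].
#' @return List with `data` (feature tibble: `sample_id`, `storage_day`,
#'   the feature columns, `tvbn`) and `truth` (informative indices, response
#'   parameters, realised `y`).
#' @export
generate_feature_table <- function(config) {
  withr::with_seed(config$seed, {
    prof <- generate_tvbn_impl(config)
    y <- prof$tvbn
    n <- length(y)
    p <- config$n_variables
    info <- config$informative_indices
    span <- config$tvbn_end - config$tvbn_start

    pars <- tibble::tibble(
      index = info,
      amplitude = sample(c(-1, 1), length(info), replace = TRUE),
      midpoint = runif(
        length(info),
        config$tvbn_start + 0.45 * span,
        config$tvbn_start + 0.55 * span
      ),
      slope = runif(length(info), 0.05 * span, 0.08 * span)
    )

    x <- matrix(rnorm(n * p), n, p)
    for (j in seq_len(nrow(pars))) {
      resp <- switch(config$response_kind,
        sigmoid = sigmoid((y - pars$midpoint[j]) / pars$slope[j]),
        linear = (y - config$tvbn_start) / span,
        quadratic = ((y - pars$midpoint[j]) / span)^2
      )
      x[, pars$index[j]] <- pars$amplitude[j] * resp +
        rnorm(n, 0, config$feature_noise_sd)
    }

    fnames <- if (p == 90) {
      csa_feature_names(grid_layout(300, 300))
    } else {
      sprintf("x%03d", seq_len(p))
    }
    colnames(x) <- fnames
    data <- dplyr::bind_cols(
      prof[c("sample_id", "storage_day")],
      tibble::as_tibble(x),
      prof["tvbn"]
    )
    list(
      data = data,
      truth = list(
        informative_indices = info,
        informative_names = fnames[info],
        response = pars,
        response_kind = config$response_kind,
        y = y
      )
    )
  })
}

#' Render a before/after image pair realising given per-spot RGB deltas
#'
#' Each spot is painted as a uniform disc, so the extracted mean colour is
#' exactly the painted colour and [extract_feature_vector()] recovers the
#' requested RGB deltas exactly (derived HSV/Lab deltas follow from the
#' conversions).
#'
#' @param deltas Numeric matrix `n_spots x 3` of target (dR, dG, dB).
#' @param layout A [array_layout()].
#' @param image_shape Integer `c(height, width)` (default 300 x 300).
#' @param base_colors Optional `n_spots x 3` matrix of before-image spot
#'   colours; defaults to a fixed dye-like palette.
#' @param background Background grey level (default 230).
#' @return List with `before` and `after` image arrays (0-255).
#' @export
render_image_pair <- function(deltas, layout, image_shape = c(300, 300),
                              base_colors = NULL, background = 230) {
  ns <- n_spots(layout)
  deltas <- matrix(as.numeric(deltas), ns, 3)
  if (is.null(base_colors)) {
    base_colors <- matrix(
      c(
        180, 60, 60, 60, 160, 70, 70, 80, 180,
        170, 150, 50, 150, 60, 150, 60, 150, 150,
        120, 120, 120, 200, 120, 60, 90, 60, 140
      ),
      ncol = 3, byrow = TRUE
    )[seq_len(ns), , drop = FALSE]
  }
  after_colors <- base_colors + deltas
  if (any(after_colors < 0 | after_colors > 255)) {
    abort("Requested deltas push a spot colour outside [0, 255].")
  }
  before <- array(background, c(image_shape, 3))
  after <- array(background, c(image_shape, 3))
  for (i in seq_len(ns)) {
    mask <- build_spot_mask(layout, i, image_shape)
    for (ch in 1:3) {
      before[cbind(mask, ch)] <- base_colors[i, ch]
      after[cbind(mask, ch)] <- after_colors[i, ch]
    }
  }
  list(before = before, after = after)
}

#' Write a synthetic dataset to disk
#'
#' Writes the feature table CSV (same dialect as [write_feature_table()])
#' and a ground-truth JSON manifest.
#'
#' @param dataset Result of [generate_feature_table()].
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_synthetic_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_feature_table(dataset$data, file.path(dir, "features.csv"))
  truth <- dataset$truth
  truth$response <- as.data.frame(truth$response)
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}
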