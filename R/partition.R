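#' SPXY calibration/prediction split
#'
#' Sample-set partitioning based on joint x-y distances: the pairwise
#' distance is the Euclidean distance on autoscaled features plus the
#' absolute response difference, each normalised by its maximum
#' (`d = dx/max(dx) + dy/max(dy)`). The calibration set is seeded with the
#' two most mutually distant samples and grown by max-min selection (the
#' candidate whose minimum distance to the chosen set is largest) until it
#' holds `round(N * cal / (cal + pred))` samples (half-up rounding); the
#' remainder is the prediction set. Ties are broken by lowest sample index,
#' so the split is fully deterministic.
#'
#' @param data Feature table (tibble with metadata columns) or numeric
#'   matrix of predictors.
#' @param y Response vector; taken from the table's `tvbn` column when
#'   omitted.
#' @param ratio Integer pair giving the calibration:prediction ratio
#'   (default `c(3, 2)`, the study's 48/32 split at N = 80).
#' @return An object of class `spxy_partition` with `calibration` and
#'   `prediction` index vectors.
#' @export
spxy_partition <- function(data, y = NULL, ratio = c(3, 2)) {
  x <- feature_matrix(data)
  if (is.null(y)) y <- data$tvbn
  x <- check_xy(x, y)
  n <- nrow(x)
  if (n < 2) abort("SPXY needs at least 2 samples.")
  n_cal <- as.integer(round_half_up(n * ratio[1] / sum(ratio)))
  n_cal <- min(max(n_cal, 1L), n - 1L)

  dx <- as.matrix(stats::dist(autoscale(x)$x))
  dy <- abs(outer(y, y, "-"))
  mx <- max(dx)
  my <- max(dy)
  d <- (if (mx > 0) dx / mx else 0) + (if (my > 0) dy / my else 0)

  if (max(d) == 0) {
    warn("All samples identical under the joint x-y metric; splitting in index order.")
    sel <- seq_len(n_cal)
  } else {
    # Seed pair: maximum joint distance, lowest indices on ties.
    flat <- which(d == max(d), arr.ind = TRUE)
    flat <- flat[order(pmin(flat[, 1], flat[, 2]), pmax(flat[, 1], flat[, 2])), ,
      drop = FALSE
    ]
    sel <- sort(unique(as.integer(flat[1, ])))
    while (length(sel) < n_cal) {
      remaining <- setdiff(seq_len(n), sel)
      min_d <- apply(d[remaining, sel, drop = FALSE], 1, min)
      sel <- c(sel, remaining[which.max(min_d)])
    }
    sel <- head(sel, n_cal)
  }
  structure(
    list(
      calibration = sort(as.integer(sel)),
      prediction = setdiff(seq_len(n), sel),
      ratio = as.integer(ratio),
      n = n
    ),
    class = "spxy_partition"
  )
}

#' @export
print.spxy_partition <- function(x, ...) {
  cat(sprintf(
    "<spxy_partition> %d calibration / %d prediction (ratio %d:%d)\n",
    length(x$calibration), length(x$prediction), x$ratio[1], x$ratio[2]
  ))
  invisible(x)
}

#' @exportS3Method
tidy.spxy_partition <- function(x, ...) {
  tibble::tibble(
    index = c(x$calibration, x$prediction),
    set = rep(c("calibration", "prediction"),
      c(length(x$calibration), length(x$prediction))
    )
  ) |> dplyr::arrange(.data$index)
}

#' Write a partition as a two-column CSV
#'
#' @param partition An `spxy_partition`.
#' @param path Output CSV path.
#' @param sample_ids Optional ids; defaults to the sample index.
#' @export
write_partition <- function(partition, path, sample_ids = NULL) {
  out <- tidy(partition)
  out$sample_id <- if (is.null(sample_ids)) {
    as.character(out$index)
  } else {
    sample_ids[out$index]
  }
  readr::write_csv(out[c("sample_id", "set")], path)
  invisible(path)
}

#' Disjoint cross-validation folds
#'
#' @param n Number of samples.
#' @param k Number of folds (`2 <= k <= n`).
#' @param seed Integer seed for the shuffle.
#' @return List of `k` disjoint validation index vectors whose sizes differ
#'   by at most one and whose union is `1:n`.
#' @export
kfold_indices <- function(n, k = 5, seed = 1) {
  if (k < 2 || k > n) abort("`k` must satisfy 2 <= k <= n.")
  perm <- withr::with_seed(seed, sample.int(n))
  sizes <- rep(n %/% k, k) + c(rep(1L, n %% k), rep(0L, k - n %% k))
  split(perm, rep(seq_len(k), times = sizes))
}
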