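new_selection <- function(algorithm, selected, scores, settings, p, extra = list()) {
  selected <- sort(as.integer(selected))
  structure(
    c(
      list(
        algorithm = algorithm,
        selected = selected,
        scores = scores, # tibble: index, variable, score (+ extras)
        settings = settings,
        p = as.integer(p),
        retained_fraction = retained_fraction_report(length(selected), p)
      ),
      extra
    ),
    class = "csa_selection"
  )
}

#' @export
print.csa_selection <- function(x, ...) {
  cat(sprintf(
    "<csa_selection> %s: %d of %d variables retained (%.2f%%)\n",
    x$algorithm, length(x$selected), x$p, x$retained_fraction
  ))
  invisible(x)
}

#' @exportS3Method
tidy.csa_selection <- function(x, ...) {
  dplyr::mutate(x$scores, selected = .data$index %in% x$selected)
}

#' @exportS3Method
glance.csa_selection <- function(x, ...) {
  tibble::tibble(
    algorithm = x$algorithm,
    n_selected = length(x$selected),
    p = x$p,
    retained_fraction = x$retained_fraction
  )
}

#' Percentage of variables retained by a selection
#'
#' Reported as `100 * selected / total`, rounded half-up to two decimals
#' (13 of 90 gives 14.44, 30 of 90 gives 33.33).
#'
#' @param selection A `csa_selection`, or the number of selected variables.
#' @param p_total Total variable count.
#' @return Percentage, 2 decimals.
#' @export
retained_fraction_report <- function(selection, p_total) {
  k <- if (inherits(selection, "csa_selection")) {
    length(selection$selected)
  } else {
    as.numeric(selection)
  }
  if (p_total <= 0) abort("`p_total` must be positive.")
  if (k > p_total) abort("Selected count exceeds the variable total.")
  round_half_up(100 * k / p_total, 2)
}

#' Write a selection result as JSON
#'
#' Serialises the retained indices, per-variable scores and the settings
#' echo; the score profile is also written as CSV next to it for plotting.
#'
#' @param selection A `csa_selection`.
#' @param path JSON output path.
#' @export
write_selection <- function(selection, path) {
  jsonlite::write_json(
    list(
      algorithm = selection$algorithm,
      selected_indices = selection$selected,
      retained_fraction = selection$retained_fraction,
      settings = selection$settings,
      scores = as.data.frame(selection$scores)
    ),
    path,
    auto_unbox = TRUE, digits = NA
  )
  readr::write_csv(selection$scores, sub("\\.json$", "_scores.csv", path))
  invisible(path)
}

#' Uninformative variable elimination (UVE)
#'
#' Appends artificial random variables of negligible amplitude to the
#' autoscaled predictors, fits leave-one-out PLS models, and scores every
#' variable by the stability of its regression coefficient across the
#' leave-one-out fits, `s_j = mean(b_j) / sd(b_j)`. The cutoff is a high
#' quantile (0.99 by default) of the absolute stabilities of the artificial
#' variables; real variables whose |stability| exceeds it are retained.
#'
#' @param x Feature table or predictor matrix (calibration set only).
#' @param y Response vector.
#' @param n_artificial Number of artificial noise variables L (default p).
#' @param noise_scale Amplitude of the artificial variables relative to the
#'   autoscaled predictors (default 1e-10, so they cannot perturb the fit).
#' @param cutoff_quantile Quantile of |artificial stability| used as cutoff
#'   (default 0.99).
#' @param n_lv Latent variables for the internal PLS fits (default 5,
#'   clipped to the data).
#' @param seed RNG seed for the artificial variables.
#' @return A `csa_selection` with stability scores and the cutoff.
#' @export
uve_select <- function(x, y = NULL, n_artificial = NULL, noise_scale = 1e-10,
                       cutoff_quantile = 0.99, n_lv = 5, seed = 1) {
  if (is.null(y)) y <- x$tvbn
  xm <- feature_matrix(x)
  xm <- check_xy(xm, y)
  n <- nrow(xm)
  p <- ncol(xm)
  if (cutoff_quantile <= 0 || cutoff_quantile > 1) {
    abort("`cutoff_quantile` must lie in (0, 1].")
  }
  L <- as.integer(n_artificial %||% p)
  if (L < 1) abort("`n_artificial` must be >= 1.")
  n_lv <- min(n_lv, n - 2, p)

  xs <- autoscale(xm)$x
  art <- withr::with_seed(seed, {
    matrix(runif(n * L, -0.5, 0.5), n, L) * noise_scale
  })
  aug <- cbind(xs, art)

  betas <- matrix(0, n, p + L)
  for (i in seq_len(n)) {
    fit <- pls_fit(aug[-i, , drop = FALSE], y[-i], n_lv = n_lv, scale = FALSE)
    betas[i, ] <- fit$coefficients # scaled-space coefficients
  }
  b_mean <- colMeans(betas)
  b_sd <- apply(betas, 2, sd)
  stability <- b_mean / b_sd
  degenerate <- b_sd < .Machine$double.eps
  if (any(degenerate)) {
    warn("Some coefficient sequences have zero spread; stability set to +/-Inf.")
    stability[degenerate] <- sign(b_mean[degenerate]) * Inf
    stability[degenerate & b_mean == 0] <- Inf
  }
  cutoff <- quantile(abs(stability[(p + 1):(p + L)]), cutoff_quantile,
    names = FALSE
  )
  selected <- which(abs(stability[seq_len(p)]) > cutoff)
  scores <- tibble::tibble(
    index = seq_len(p),
    variable = colnames(xm) %||% sprintf("x%03d", seq_len(p)),
    score = stability[seq_len(p)]
  )
  new_selection(
    "UVE", selected, scores,
    settings = list(
      n_artificial = L, noise_scale = noise_scale,
      cutoff_quantile = cutoff_quantile, n_lv = n_lv, seed = seed
    ),
    p = p,
    extra = list(
      cutoff = cutoff,
      artificial_stability = stability[(p + 1):(p + L)]
    )
  )
}

# EDF retention schedule: r_i = a * exp(-k * i) with r_1 * p = p and
# r_N * p = 2, so counts run from all p variables down to 2.
cars_edf_counts <- function(p, n_runs) {
  if (n_runs < 2) abort("CARS needs at least 2 Monte Carlo runs.")
  k <- log(p / 2) / (n_runs - 1)
  a <- exp(k)
  r <- a * exp(-k * seq_len(n_runs))
  # epsilon guards the exact endpoints (r_1 p = p, r_N p = 2) against
  # floating-point excess before ceiling
  pmin(p, pmax(2L, ceiling(r * p - 1e-9)))
}

#' Competitive adaptive reweighted sampling (CARS)
#'
#' Each Monte Carlo run fits a PLS model on a random subsample of the
#' calibration rows restricted to the currently retained variables, ranks
#' variables by |regression coefficient| (autoscaled space), enforces the
#' exponentially declining retention count (from all p down to 2 across the
#' runs), then applies adaptive reweighted sampling: variables are resampled
#' with replacement with probability proportional to |coefficient| and the
#' sampled set is kept. Every run's subset is scored by k-fold RMSECV on
#' the full calibration set; the subset with the minimum RMSECV wins (ties
#' to fewer variables, then the earlier run).
#'
#' @param x Feature table or predictor matrix (calibration set only).
#' @param y Response vector.
#' @param n_mc_runs Monte Carlo runs N (default 25).
#' @param cv_folds Folds for the per-run RMSECV (default 5).
#' @param subsample_share Fraction of calibration rows fitted per run
#'   (default 0.8).
#' @param n_lv Latent-variable cap for internal PLS fits (default 5).
#' @param seed RNG seed.
#' @return A `csa_selection`; scores are selection frequencies across runs,
#'   and the per-run history (counts, RMSECV) is attached.
#' @export
cars_select <- function(x, y = NULL, n_mc_runs = 25, cv_folds = 5,
                        subsample_share = 0.8, n_lv = 5, seed = 1) {
  if (is.null(y)) y <- x$tvbn
  xm <- feature_matrix(x)
  xm <- check_xy(xm, y)
  n <- nrow(xm)
  p <- ncol(xm)
  if (p < 2) abort("CARS needs at least 2 variables.")
  if (subsample_share <= 0 || subsample_share > 1) {
    abort("`subsample_share` must lie in (0, 1].")
  }
  counts <- cars_edf_counts(p, n_mc_runs)
  folds <- kfold_indices(n, cv_folds, derive_seed(seed, 1))

  withr::with_seed(derive_seed(seed, 2), {
    retained <- seq_len(p)
    subsets <- vector("list", n_mc_runs)
    run_rmsecv <- numeric(n_mc_runs)
    n_sub <- max(2, round(subsample_share * n))
    for (i in seq_len(n_mc_runs)) {
      rows <- sample.int(n, n_sub)
      a <- min(n_lv, length(retained), n_sub - 1)
      fit <- pls_fit(xm[rows, retained, drop = FALSE], y[rows], n_lv = a)
      wgt <- abs(fit$coefficients)
      # EDF cut: keep the top-|beta| variables at the scheduled count
      keep_n <- min(counts[i], length(retained))
      ord <- order(wgt, decreasing = TRUE)
      edf_kept <- retained[ord[seq_len(keep_n)]]
      edf_w <- wgt[ord[seq_len(keep_n)]]
      # ARS: weighted resampling with replacement among the survivors
      retained <- if (sum(edf_w) > 0) {
        sort(unique(sample(edf_kept, keep_n, replace = TRUE, prob = edf_w)))
      } else {
        sort(edf_kept)
      }
      if (length(retained) < 2) {
        retained <- sort(edf_kept[seq_len(min(2, length(edf_kept)))])
      }
      subsets[[i]] <- retained
      a_cv <- min(n_lv, length(retained))
      run_rmsecv[i] <- rmsecv(
        xm[, retained, drop = FALSE], y, folds,
        function(xt, yt) pls_fit(xt, yt, n_lv = min(a_cv, nrow(xt) - 1))
      )
    }
    sizes <- lengths(subsets)
    best <- order(run_rmsecv, sizes, seq_len(n_mc_runs))[1]
    freq <- tabulate(unlist(subsets), nbins = p) / n_mc_runs
    scores <- tibble::tibble(
      index = seq_len(p),
      variable = colnames(xm) %||% sprintf("x%03d", seq_len(p)),
      score = freq
    )
    new_selection(
      "CARS", subsets[[best]], scores,
      settings = list(
        n_mc_runs = n_mc_runs, cv_folds = cv_folds,
        subsample_share = subsample_share, n_lv = n_lv, seed = seed
      ),
      p = p,
      extra = list(
        history = tibble::tibble(
          run = seq_len(n_mc_runs),
          edf_count = counts,
          n_retained = sizes,
          rmsecv = run_rmsecv
        ),
        best_run = best
      )
    )
  })
}

#' Random frog variable selection
#'
#' A reversible-jump MCMC-flavoured search over variable subsets. From a
#' random initial subset of size Q, each iteration draws a candidate
#' dimension from Normal(Q, theta * Q) (rounded, clipped to `[1, p]`),
#' builds a candidate subset — shrinking by dropping the weakest
#' |coefficient| members, or growing by pooling the current subset with a
#' random draw of outside variables (3 per added slot) and keeping the
#' strongest — and accepts it outright when its k-fold RMSECV improves, or
#' with probability `eta * RMSECV_old / RMSECV_new` otherwise. A variable's
#' score is the fraction of iterations whose accepted subset contains it;
#' the final selection is the `top_k` by that probability.
#'
#' @param x Feature table or predictor matrix (calibration set only).
#' @param y Response vector.
#' @param n_iterations Iterations N (default 10000, the study setting;
#'   smaller values are typical for desk-scale work).
#' @param q_init Initial subset size Q (default 2).
#' @param theta Dimension-proposal variation factor (default 0.2).
#' @param eta Acceptance smoothing for worse candidates (default 0.1).
#' @param top_k Number of variables in the final selection (default 30).
#' @param cv_folds Folds for the RMSECV comparisons (default 5).
#' @param n_lv Latent-variable cap for internal PLS fits (default 5).
#' @param seed RNG seed.
#' @return A `csa_selection`; scores are selection probabilities.
#' @export
random_frog_select <- function(x, y = NULL, n_iterations = 10000, q_init = 2,
                               theta = 0.2, eta = 0.1, top_k = 30,
                               cv_folds = 5, n_lv = 5, seed = 1) {
  if (is.null(y)) y <- x$tvbn
  xm <- feature_matrix(x)
  xm <- check_xy(xm, y)
  n <- nrow(xm)
  p <- ncol(xm)
  if (q_init < 1 || q_init > p) abort("`q_init` must lie in 1..p.")
  if (theta <= 0) abort("`theta` must be > 0.")
  folds <- kfold_indices(n, cv_folds, derive_seed(seed, 3))
  q_max <- p

  subset_rmsecv <- function(vars) {
    rmsecv(
      xm[, vars, drop = FALSE], y, folds,
      function(xt, yt) {
        pls_fit(xt, yt, n_lv = min(n_lv, length(vars), nrow(xt) - 1))
      }
    )
  }
  rank_by_beta <- function(vars, rows_y = y) {
    fit <- pls_fit(xm[, vars, drop = FALSE], rows_y,
      n_lv = min(n_lv, length(vars), n - 1)
    )
    vars[order(abs(fit$coefficients), decreasing = TRUE)]
  }

  withr::with_seed(derive_seed(seed, 4), {
    current <- sort(sample.int(p, q_init))
    current_err <- subset_rmsecv(current)
    counts <- integer(p)
    for (it in seq_len(n_iterations)) {
      q_now <- length(current)
      q_star <- round(rnorm(1, q_now, theta * q_now))
      q_star <- min(max(q_star, 1), q_max)
      if (q_star == q_now) {
        cand <- current
      } else if (q_star < q_now) {
        cand <- sort(head(rank_by_beta(current), q_star))
      } else {
        outside <- setdiff(seq_len(p), current)
        pool <- sample(outside, min(3 * (q_star - q_now), length(outside)))
        ranked <- rank_by_beta(sort(c(current, pool)))
        cand <- sort(head(ranked, min(q_star, length(ranked))))
      }
      if (!identical(cand, current)) {
        cand_err <- subset_rmsecv(cand)
        accept <- cand_err <= current_err ||
          runif(1) < eta * current_err / cand_err
        if (accept) {
          current <- cand
          current_err <- cand_err
        }
      }
      counts[current] <- counts[current] + 1L
    }
    prob <- counts / n_iterations
    selected <- order(prob, -seq_len(p), decreasing = TRUE)[seq_len(min(top_k, p))]
    scores <- tibble::tibble(
      index = seq_len(p),
      variable = colnames(xm) %||% sprintf("x%03d", seq_len(p)),
      score = prob
    )
    new_selection(
      "random frog", selected, scores,
      settings = list(
        n_iterations = n_iterations, q_init = q_init, theta = theta,
        eta = eta, top_k = top_k, cv_folds = cv_folds, n_lv = n_lv,
        seed = seed
      ),
      p = p
    )
  })
}
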