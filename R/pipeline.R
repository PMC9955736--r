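default_roster <- c(
  "PLS", "RF-PLS", "UVE-PLS", "CARS-PLS",
  "SVM", "RF-SVM", "UVE-SVM", "CARS-SVM"
)

#' Configure the end-to-end model-comparison pipeline
#'
#' @param data Feature table tibble (with `tvbn`), or `NULL` to generate
#'   one from `synthetic`.
#' @param synthetic A [synthetic_config()] used when `data` is `NULL`.
#' @param ratio SPXY calibration:prediction ratio (default 3:2).
#' @param partition Optional precomputed [spxy_partition()] to reuse
#'   (e.g. from an earlier run); computed from the data when `NULL`.
#' @param roster Model roster; any of `"PLS"`, `"SVM"` optionally prefixed
#'   by a selector (`"RF-"`, `"UVE-"`, `"CARS-"`). Default: the full
#'   eight-model comparison.
#' @param pls,svr,uve,cars,frog Named lists of per-stage settings
#'   overriding the stage defaults (e.g. `svr = list(g_grid = 2^(-4:4))`,
#'   `frog = list(n_iterations = 1000)`).
#' @param seed Master seed; every stochastic stage draws a deterministic
#'   sub-seed from it.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(data = NULL, synthetic = synthetic_config(),
                            ratio = c(3, 2), partition = NULL,
                            roster = default_roster,
                            pls = list(), svr = list(), uve = list(),
                            cars = list(), frog = list(), seed = 1) {
  if (length(roster) == 0) abort("Model roster must be non-empty.")
  bad <- setdiff(roster, default_roster)
  if (length(bad)) {
    abort(paste0("Unknown roster entries: ", paste(bad, collapse = ", ")))
  }
  structure(
    list(
      data = data, synthetic = synthetic, ratio = ratio,
      partition = partition, roster = roster,
      pls = pls, svr = svr, uve = uve, cars = cars, frog = frog,
      seed = as.integer(seed)
    ),
    class = "pipeline_config"
  )
}

roster_selector <- function(entry) {
  switch(sub("-(PLS|SVM)$", "", entry),
    "RF" = "frog", "UVE" = "uve", "CARS" = "cars",
    NA_character_
  )
}

roster_family <- function(entry) sub("^(RF|UVE|CARS)-", "", entry)

#' Run the full calibration comparison
#'
#' Executes the whole study design: obtain a feature table (supplied or
#' synthetic), split it with SPXY, run each selector once on the
#' calibration set only, fit a PLS (with cross-validated latent-variable
#' choice) and an SVR (with (g, c) grid search) per roster entry on the
#' selected variables, evaluate every model on the untouched prediction
#' set, and run the runs test on the full-variable PLS calibration
#' residuals. Fully reproducible from `(config, seed)`.
#'
#' @param config A [pipeline_config()].
#' @return A `csa_comparison` object: per-model evaluation table, fitted
#'   models, selections, runs test and best-model verdict (lowest RMSEP,
#'   ties to highest RPD).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  seed <- config$seed
  truth <- NULL
  data <- config$data
  if (is.null(data)) {
    syn <- config$synthetic
    syn$seed <- derive_seed(seed, 10)
    gen <- generate_feature_table(syn)
    data <- gen$data
    truth <- gen$truth
  }
  y <- data$tvbn
  if (is.null(y) || anyNA(y)) abort("Feature table must carry reference `tvbn`.")
  x <- feature_matrix(data)

  part <- config$partition %||% spxy_partition(data, y, ratio = config$ratio)
  cal <- part$calibration
  pred <- part$prediction
  x_cal <- x[cal, , drop = FALSE]
  y_cal <- y[cal]
  x_pred <- x[pred, , drop = FALSE]
  y_pred <- y[pred]

  # One selection per algorithm, shared between its PLS and SVM branches.
  selectors_needed <- unique(stats::na.omit(
    vapply(config$roster, roster_selector, "")
  ))
  selections <- list()
  for (sel in selectors_needed) {
    selections[[sel]] <- switch(sel,
      uve = do.call(uve_select, c(
        list(x = x_cal, y = y_cal, seed = derive_seed(seed, 20)),
        config$uve
      )),
      cars = do.call(cars_select, c(
        list(x = x_cal, y = y_cal, seed = derive_seed(seed, 21)),
        config$cars
      )),
      frog = do.call(random_frog_select, c(
        list(x = x_cal, y = y_cal, seed = derive_seed(seed, 22)),
        config$frog
      ))
    )
  }

  fit_one <- function(entry) {
    sel <- roster_selector(entry)
    vars <- if (is.na(sel)) seq_len(ncol(x)) else selections[[sel]]$selected
    if (length(vars) == 0) vars <- seq_len(ncol(x)) # selector kept nothing
    xc <- x_cal[, vars, drop = FALSE]
    xp <- x_pred[, vars, drop = FALSE]
    model <- if (roster_family(entry) == "PLS") {
      args <- config$pls
      nl <- do.call(select_nlv, c(
        list(
          x = xc, y = y_cal,
          max_nlv = args$max_nlv %||% 10,
          k = args$k %||% 5, seed = derive_seed(seed, 30)
        )
      ))
      pls_fit(xc, y_cal, n_lv = nl$best)
    } else {
      args <- config$svr
      gs <- grid_search_svr(
        xc, y_cal,
        g_grid = args$g_grid %||% 2^(-8:8),
        c_grid = args$c_grid %||% 2^(-8:8),
        k = args$k %||% 5,
        epsilon = args$epsilon %||% 0.1,
        seed = derive_seed(seed, 31)
      )
      svr_fit(xc, y_cal,
        gamma = gs$best_gamma, cost = gs$best_cost,
        epsilon = args$epsilon %||% 0.1
      )
    }
    evaluate_model(model, xc, y_cal, xp, y_pred, label = entry)
  }

  evaluations <- stats::setNames(lapply(config$roster, fit_one), config$roster)

  # Nonlinearity diagnosis on the full-variable PLS calibration residuals.
  full_nlv <- select_nlv(x_cal, y_cal,
    max_nlv = config$pls$max_nlv %||% 10,
    k = config$pls$k %||% 5, seed = derive_seed(seed, 30)
  )
  full_pls <- pls_fit(x_cal, y_cal, n_lv = full_nlv$best)
  # a (near-)perfect linear fit leaves single-signed numerical residuals;
  # the runs test is then undefined and no nonlinearity can be claimed
  rt <- tryCatch(
    runs_test(y_cal - full_pls$fitted),
    error = function(e) NULL
  )

  results <- dplyr::bind_rows(lapply(evaluations, glance))
  best <- results |>
    dplyr::arrange(.data$RMSEP, dplyr::desc(.data$RPD)) |>
    dplyr::slice(1)

  structure(
    list(
      results = results,
      evaluations = evaluations,
      selections = selections,
      runs_test = rt,
      best_model = best$model,
      partition = part,
      truth = truth,
      config = config
    ),
    class = "csa_comparison"
  )
}

#' @export
print.csa_comparison <- function(x, ...) {
  rt_txt <- if (is.null(x$runs_test)) {
    "runs-test n/a"
  } else {
    sprintf(
      "runs-test z = %.2f (%s)", x$runs_test$z,
      if (x$runs_test$nonlinear) "nonlinear" else "linear"
    )
  }
  cat(sprintf(
    "<csa_comparison> %d models | best: %s | %s\n",
    nrow(x$results), x$best_model, rt_txt
  ))
  print(x$results)
  invisible(x)
}

#' @exportS3Method
tidy.csa_comparison <- function(x, ...) x$results

#' @exportS3Method
glance.csa_comparison <- function(x, ...) {
  tibble::tibble(
    best_model = x$best_model,
    best_rmsep = min(x$results$RMSEP),
    runs_z = if (is.null(x$runs_test)) NA_real_ else x$runs_test$z,
    nonlinear = if (is.null(x$runs_test)) NA else x$runs_test$nonlinear,
    n_models = nrow(x$results)
  )
}

#' Write the comparison report
#'
#' Emits the Table-2-style CSV (one row per model, sorted by RMSEP
#' ascending) and a short text summary.
#'
#' @param comparison A `csa_comparison`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_comparison_report <- function(comparison, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  out <- dplyr::arrange(comparison$results, .data$RMSEP)
  readr::write_csv(out, file.path(dir, "comparison.csv"))
  rt <- comparison$runs_test
  rt_line <- if (is.null(rt)) {
    "Runs test: not applicable (single-signed residuals)"
  } else {
    sprintf(
      "Runs test: z = %.3f (R = %d, n+ = %d, n- = %d) -> %s",
      rt$z, rt$runs, rt$n_positive, rt$n_negative,
      if (rt$nonlinear) "nonlinear (|z| > 1.96)" else "not flagged"
    )
  }
  writeLines(
    c(
      sprintf("Best model: %s", comparison$best_model),
      rt_line,
      "",
      sprintf(
        "%-10s Rp = %.3f  RMSEP = %.3f  RPD = %.2f (%s)",
        out$model, out$Rp, out$RMSEP, out$RPD, classify_rpd(out$RPD)
      )
    ),
    file.path(dir, "summary.txt")
  )
  invisible(dir)
}
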