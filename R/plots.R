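#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_line geom_col
#'   geom_abline geom_hline geom_tile labs facet_wrap scale_fill_viridis_c
NULL

#' @exportS3Method
autoplot.csa_evaluation <- function(object, ...) {
  ggplot(object$predictions, aes(.data$reference, .data$predicted,
    colour = .data$set
  )) +
    geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey50") +
    geom_point(alpha = 0.8) +
    labs(
      title = sprintf(
        "%s: Rp = %.2f, RMSEP = %.2f, RPD = %.2f",
        object$label, object$Rp, object$RMSEP, object$RPD
      ),
      x = "Reference TVB-N (mg/100 g)", y = "Predicted TVB-N (mg/100 g)",
      colour = NULL
    )
}

#' @exportS3Method
autoplot.csa_selection <- function(object, ...) {
  d <- tidy(object)
  p <- ggplot(d, aes(.data$index, .data$score, fill = .data$selected)) +
    geom_col() +
    labs(
      title = sprintf(
        "%s: %d of %d variables (%.2f%%)",
        object$algorithm, length(object$selected), object$p,
        object$retained_fraction
      ),
      x = "Variable index",
      y = switch(object$algorithm,
        "UVE" = "Coefficient stability",
        "CARS" = "Selection frequency",
        "Selection probability"
      ),
      fill = "Selected"
    )
  if (!is.null(object$cutoff) && is.finite(object$cutoff)) {
    p <- p +
      geom_hline(yintercept = c(-1, 1) * object$cutoff, linetype = 2)
  }
  p
}

#' @exportS3Method
autoplot.svr_grid <- function(object, ...) {
  ggplot(object$grid, aes(log2(.data$gamma), log2(.data$cost),
    fill = .data$rmsecv
  )) +
    geom_tile() +
    scale_fill_viridis_c() +
    labs(
      title = sprintf(
        "SVR grid search: best g = %g, c = %g",
        object$best_gamma, object$best_cost
      ),
      x = "log2(g)", y = "log2(c)", fill = "RMSECV"
    )
}

#' @exportS3Method
autoplot.csa_comparison <- function(object, ...) {
  d <- dplyr::arrange(object$results, .data$RMSEP)
  d$model <- factor(d$model, levels = d$model)
  ggplot(d, aes(.data$model, .data$RMSEP, fill = .data$model == object$best_model)) +
    geom_col(show.legend = FALSE) +
    labs(
      title = sprintf("Model comparison (best: %s)", object$best_model),
      x = NULL, y = "RMSEP (mg/100 g)"
    )
}

#' Plot an RMSECV curve from latent-variable selection
#'
#' @param nlv Result of [select_nlv()].
#' @return A ggplot.
#' @export
plot_nlv_curve <- function(nlv) {
  ggplot(nlv$curve, aes(.data$n_lv, .data$rmsecv)) +
    geom_line() +
    geom_point() +
    geom_point(
      data = nlv$curve[nlv$best, ], colour = "red", size = 3
    ) +
    labs(x = "Latent variables", y = "RMSECV (mg/100 g)")
}
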