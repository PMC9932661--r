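# ggplot2 visualizations for the main result types.

#' Plot prediction intervals along samples
#'
#' Ribbon of the prediction interval with point predictions and
#' (optionally) the true responses overlaid, in the style of per-sample
#' interval panels.
#'
#' @param object A `drp_intervals` tibble from [prediction_interval()].
#' @param truth Optional numeric vector of true responses (same order).
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.drp_intervals <- function(object, truth = NULL, ...) {
  df <- dplyr::mutate(tibble::as_tibble(object), index = dplyr::row_number())
  if (!is.null(truth)) df$truth <- truth
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$index)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
                         fill = "pink", alpha = 0.6) +
    ggplot2::geom_line(ggplot2::aes(y = .data$point), colour = "steelblue") +
    ggplot2::labs(x = "sample", y = "response (IC50)",
                  title = paste0(unique(df$level) * 100, "% prediction intervals"))
  if (!is.null(truth)) {
    p <- p + ggplot2::geom_point(ggplot2::aes(y = .data$truth), colour = "firebrick", size = 1)
  }
  p
}

#' Observed-versus-predicted scatter for a CV report
#'
#' @param object A `drp_cv`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.drp_cv <- function(object, ...) {
  m <- object$metrics
  ggplot2::ggplot(object$predictions,
                  ggplot2::aes(x = .data$truth, y = .data$estimate)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_point(alpha = 0.7, colour = "steelblue") +
    ggplot2::labs(x = "observed", y = "predicted",
                  title = sprintf("%d-fold CV: R² = %.3f, RMSE = %.3f",
                                  object$k, m$r2, m$rmse))
}

#' Feature-importance bars for a boosted ensemble
#'
#' @param object A `drp_boost`.
#' @param top_n How many features to show (default 20).
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.drp_boost <- function(object, top_n = 20, ...) {
  imp <- head(feature_importance_gain(object), top_n)
  imp <- imp[imp$gain > 0, ]
  ggplot2::ggplot(imp, ggplot2::aes(x = stats::reorder(.data$feature, .data$gain),
                                    y = .data$gain)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "total split gain")
}

#' Candidate-drug intervals for a recommendation
#'
#' @param object A `drp_recommendation`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.drp_recommendation <- function(object, ...) {
  df <- object$candidates
  ggplot2::ggplot(df, ggplot2::aes(x = .data$drug)) +
    ggplot2::geom_linerange(ggplot2::aes(ymin = .data$lower, ymax = .data$upper,
                                         colour = .data$high_risk), linewidth = 1) +
    ggplot2::geom_point(ggplot2::aes(y = .data$point), shape = 1, size = 3,
                        colour = "firebrick") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey30", `TRUE` = "darkorange"),
                                 name = "high risk") +
    ggplot2::labs(x = NULL, y = "predicted IC50",
                  title = paste0("Recommended: ", object$recommended))
}
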