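#' Plot aggregated scenario results
#'
#' For depth-grid designs (A1/A2) the chosen metric is drawn against the
#' training-set read depth on a log axis, one line per marker density, with
#' array cells shown as horizontal dashed reference lines. For budget designs
#' (A3/A4) the x axis is the set size that the budget is spread over.
#'
#' @param object A `gs_summary` from [aggregate_scenarios()].
#' @param metric One of `"accuracy"`, `"bias"`, `"response"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gs_summary <- function(object, metric = c("accuracy", "bias", "response"),
                                ...) {
  metric <- match.arg(metric)
  if (!metric %in% names(object)) {
    abort(sprintf("Metric `%s` is not present in these results.", metric))
  }
  df <- dplyr::mutate(object, density = factor(.data$markers))
  design <- df$design[1]

  if (design %in% c("A1", "A2")) {
    gbs <- dplyr::filter(df, .data$platform_train == "gbs")
    arr <- dplyr::filter(df, .data$platform_train == "array")
    p <- ggplot2::ggplot(
      gbs,
      ggplot2::aes(
        x = .data$x_train, y = .data[[metric]],
        colour = .data$density, group = .data$density
      )
    ) +
      ggplot2::geom_line() +
      ggplot2::geom_point() +
      ggplot2::scale_x_log10() +
      ggplot2::labs(
        x = "genome-wide read depth x (training)", y = metric,
        colour = "markers"
      )
    if (nrow(arr) > 0) {
      p <- p + ggplot2::geom_hline(
        data = arr,
        ggplot2::aes(yintercept = .data[[metric]], colour = .data$density),
        linetype = "dashed"
      )
    }
  } else {
    xvar <- if (design == "A4") "n_predict" else "n_train"
    # A3 varies the prediction platform, A4 the training platform.
    df$variant <- if (design == "A3") df$platform_predict else df$platform_train
    p <- ggplot2::ggplot(
      df,
      ggplot2::aes(
        x = .data[[xvar]], y = .data[[metric]],
        colour = .data$density,
        linetype = .data$variant,
        group = interaction(.data$density, .data$variant)
      )
    ) +
      ggplot2::geom_line() +
      ggplot2::geom_point() +
      ggplot2::scale_x_log10() +
      ggplot2::labs(
        x = sprintf("%s (fixed total %sx budget)", xvar, df$total_x[1]),
        y = metric, colour = "markers",
        linetype = if (design == "A3") "prediction" else "training"
      )
  }
  p + ggplot2::theme_minimal()
}

#' Plot per-replicate scenario results
#'
#' Thin wrapper that aggregates and dispatches to [autoplot.gs_summary()],
#' overlaying the replicate-level points.
#'
#' @param object A `gs_scenarios` tibble from [run_scenario()].
#' @inheritParams autoplot.gs_summary
#' @return A ggplot object.
#' @export
autoplot.gs_scenarios <- function(object,
                                  metric = c("accuracy", "bias", "response"),
                                  ...) {
  metric <- match.arg(metric)
  autoplot(aggregate_scenarios(object), metric = metric)
}

#' Scatter of estimated against true breeding values
#'
#' Visual check of accuracy (correlation) and bias (slope of the TBV-on-EBV
#' regression, drawn as a line; the dashed identity line marks no bias).
#'
#' @param tbv,ebv Numeric vectors of equal length.
#' @return A ggplot object.
#' @export
plot_prediction <- function(tbv, ebv) {
  check_tbv_ebv(tbv, ebv)
  slope <- prediction_bias(tbv, ebv)
  acc <- prediction_accuracy(tbv, ebv)
  ggplot2::ggplot(
    tibble::tibble(tbv = tbv, ebv = ebv),
    ggplot2::aes(x = .data$ebv, y = .data$tbv)
  ) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_abline(intercept = mean(tbv) - slope * mean(ebv),
                         slope = slope) +
    ggplot2::geom_abline(intercept = 0, slope = 1, linetype = "dashed") +
    ggplot2::labs(
      x = "EBV", y = "TBV",
      subtitle = sprintf("accuracy %.3f; bias slope %.3f", acc, slope)
    ) +
    ggplot2::theme_minimal()
}
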