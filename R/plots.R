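#' Speed of sound versus temperature for one or more DESs
#'
#' @param des_id DES ids to plot.
#' @param t_k Temperature grid, K.
#' @param models Models to draw (see [predict_speed()]).
#' @param data Optional experimental dataset drawn as points.
#' @param ... Passed on to [predict_speed()] (constants, density, ...).
#' @return A ggplot object (lines per model, facets per DES).
#' @export
plot_speed_temperature <- function(des_id, t_k = seq(293.15, 333.15, by = 5),
                                   models = "proposed", data = NULL, ...) {
  pred <- predict_speed(des_id, t_k = t_k, models = models, ...)
  p <- ggplot2::ggplot(pred, ggplot2::aes(x = .data$t_k, y = .data$u_ms,
                                          colour = .data$model)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(ggplot2::vars(.data$des_id), scales = "free_y") +
    ggplot2::labs(x = "T (K)", y = "u (m/s)", colour = "model") +
    ggplot2::theme_minimal()
  if (!is.null(data)) {
    p <- p + ggplot2::geom_point(
      data = filter(data, .data$des_id %in% !!des_id),
      ggplot2::aes(x = .data$T_K, y = .data$u_exp_ms),
      inherit.aes = FALSE, shape = 1
    )
  }
  p
}

#' Diagnostic plots for a model evaluation
#'
#' `type = "deviation"` draws signed relative deviations against the
#' experimental speed of sound, split by training/test tag;
#' `type = "distribution"` draws the RD% histogram.
#'
#' @param object A `des_eval` object from [evaluate_models()].
#' @param type Plot type.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.des_eval <- function(object, type = c("deviation", "distribution"),
                              ...) {
  type <- match.arg(type)
  rec <- object$records
  if (type == "deviation") {
    ggplot2::ggplot(rec, ggplot2::aes(x = .data$u_exp_ms, y = .data$rd_pct,
                                      colour = .data$split)) +
      ggplot2::geom_hline(yintercept = 0, linetype = 2) +
      ggplot2::geom_point(alpha = 0.6) +
      ggplot2::facet_wrap(ggplot2::vars(.data$model)) +
      ggplot2::labs(x = "experimental u (m/s)", y = "RD%", colour = NULL) +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(rec, ggplot2::aes(x = .data$rd_pct)) +
      ggplot2::geom_histogram(bins = 30, fill = "grey35") +
      ggplot2::facet_wrap(ggplot2::vars(.data$model)) +
      ggplot2::labs(x = "RD%", y = "count") +
      ggplot2::theme_minimal()
  }
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
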