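# ggplot2 convenience plots for the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a distance histogram
#'
#' Bars per 33-nm bin with the reserved touching column drawn at the origin.
#'
#' @param object A `syn_histogram` from [bin_by_distance()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.syn_histogram <- function(object, ...) {
  bw <- attr(object, "bin_width")
  df <- dplyr::mutate(
    tibble::as_tibble(object),
    pos = ifelse(.data$bin == 0, -bw / 2, (.data$bin - 1) * bw + bw / 2),
    touching = .data$bin == 0
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pos, y = .data$count,
                                   fill = .data$touching)) +
    ggplot2::geom_col(width = bw * 0.9, show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "orange", `FALSE` = "grey30")) +
    ggplot2::labs(x = "distance from dense projection (nm)", y = "count") +
    ggplot2::theme_minimal()
}

#' Plot a kinetic fit
#'
#' Data points (with SEM bars when present) and the fitted curve on a
#' log-time axis.
#'
#' @param object A `syn_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.syn_fit <- function(object, ...) {
  d <- tibble::as_tibble(object$data)
  tt <- exp(seq(log(max(min(d$t), 1)), log(max(d$t)), length.out = 200))
  cf <- object$coefficients
  yy <- switch(object$model,
    exp_recovery = cf["y_inf"] - (cf["y_inf"] - cf["y_0"]) * exp(-tt / cf["tau"]),
    exp_decay = cf["y_inf"] + (cf["y_0"] - cf["y_inf"]) *
      exp(-(tt - cf["t_peak"]) / cf["tau"]),
    double_exp_recovery = 1 - cf["A_f"] * exp(-tt / cf["tau_f"]) -
      cf["A_s"] * exp(-tt / cf["tau_s"])
  )
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$t, y = .data$y)) +
    ggplot2::geom_line(data = tibble::tibble(t = tt, y = yy),
                       color = "steelblue") +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "time (ms)", y = "value",
                  subtitle = sprintf("%s: tau = %s ms",
                                     object$model,
                                     paste(signif(object$tau, 3),
                                           collapse = ", "))) +
    ggplot2::theme_minimal()
  if ("sem" %in% names(d)) {
    p <- p + ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$y - .data$sem, ymax = .data$y + .data$sem),
      width = 0.02
    )
  }
  p
}

#' Plot a diameter mixture fit
#'
#' Histogram counts with the fitted mixture curve and component means.
#'
#' @param object A `syn_mixture`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.syn_mixture <- function(object, ...) {
  h <- object$histogram
  ggplot2::ggplot(h, ggplot2::aes(x = .data$mid)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$count), fill = "grey70",
                      width = object$bin_width * 0.9) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), color = "firebrick") +
    ggplot2::geom_vline(xintercept = object$means, linetype = "dashed") +
    ggplot2::labs(x = "diameter (nm)", y = "count",
                  subtitle = sprintf("k = %d, R^2 = %.2f, AIC = %.1f",
                                     object$k, object$r_squared, object$aic)) +
    ggplot2::theme_minimal()
}

#' Plot a membrane budget
#'
#' Exocytosed range vs endocytosed area by site.
#'
#' @param object A `syn_budget`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.syn_budget <- function(object, ...) {
  df <- tibble::tibble(
    side = c("exocytosed", "endocytosed", "endocytosed"),
    part = c("mean", "dense projection", "adherens junction"),
    area = c(object$exo_mean, object$endo_dp, object$endo_aj)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$side, y = .data$area,
                                   fill = .data$part)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "membrane area (nm^2)",
                  subtitle = sprintf("%g ms: %d SV equivalents recovered",
                                     object$timepoint, object$sv_equivalents)) +
    ggplot2::theme_minimal()
}
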