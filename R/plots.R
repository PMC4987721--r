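#' Plot paired empirical CDFs of adhesion sizes
#'
#' The standard display for a signed KS screen comparison: both ECDFs on a
#' log-scaled area axis.
#'
#' @param test,ref Numeric area samples (um^2).
#' @param labels Names for the two samples.
#' @return A ggplot object.
#' @export
plot_fa_ecdf <- function(test, ref, labels = c("test", "reference")) {
  df <- tibble(area_um2 = c(test, ref),
               sample = rep(labels, c(length(test), length(ref))))
  ggplot2::ggplot(df, ggplot2::aes(.data$area_um2, colour = .data$sample)) +
    ggplot2::stat_ecdf(linewidth = 0.7) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = expression("adhesion area (" * mu * m^2 * ")"),
                  y = "cumulative fraction", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @describeIn plot_fa_ecdf Autoplot method drawing the comparison behind a
#'   [signed_ks_test()] result requires the original samples; this method
#'   annotates a bare result with its statistics instead.
#' @param object A `fadyn_ks` object.
#' @param ... Unused.
#' @method autoplot fadyn_ks
#' @export
autoplot.fadyn_ks <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$signed_d, y = .data$log10_p)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(x = "signed D", y = "log10 p") +
    ggplot2::theme_minimal()
}

#' Volcano-style overview of screen hit calls
#'
#' Signed D against log10 p for the baseline-vs-control comparison,
#' coloured by hit category.
#'
#' @param calls Tibble from [score_screen()].
#' @param thresholds A [hit_thresholds()] drawn as guide lines.
#' @return A ggplot object.
#' @export
plot_screen_volcano <- function(calls, thresholds = hit_thresholds()) {
  ggplot2::ggplot(calls, ggplot2::aes(.data$d_dmso, .data$log10p_dmso,
                                      colour = .data$category)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_vline(xintercept = c(thresholds$d_decrease,
                                       thresholds$d_increase),
                        linetype = 2, colour = "grey40") +
    ggplot2::geom_hline(yintercept = c(thresholds$log10p_increase,
                                       thresholds$log10p_decrease),
                        linetype = 3, colour = "grey40") +
    ggplot2::labs(x = "signed D (baseline vs control)", y = "log10 p",
                  colour = "category") +
    ggplot2::theme_minimal()
}

#' Plot an autocorrelation curve and its exponential fit
#'
#' @param object A [force_autocorrelation()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot autocorr_fit
#' @export
autoplot.autocorr_fit <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$lag_min, .data$autocorr)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "red") +
    ggplot2::annotate("text", x = max(df$lag_min), y = max(df$autocorr),
                      hjust = 1, vjust = 1,
                      label = sprintf("halftime = %.1f min",
                                      object$halftime_min)) +
    ggplot2::labs(x = "lag (min)", y = "force autocorrelation") +
    ggplot2::theme_minimal()
}

#' Plot the mean force-per-pillar time series of a condition
#'
#' @param object A [force_timeseries_summary()] result.
#' @param frame_interval_min Minutes per frame for the time axis.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot force_summary
#' @export
autoplot.force_summary <- function(object, frame_interval_min = 5, ...) {
  df <- mutate(object$timeseries,
               t_min = (.data$frame - 1) * frame_interval_min)
  ggplot2::ggplot(df, ggplot2::aes(.data$t_min, .data$mean_force_nN)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (min)", y = "mean force per pillar (nN)") +
    ggplot2::theme_minimal()
}

#' Plot single-cell speed populations by group
#'
#' @param speeds Tibble with `group` and `speed` columns.
#' @return A ggplot object.
#' @export
plot_speed_populations <- function(speeds) {
  ggplot2::ggplot(speeds, ggplot2::aes(.data$group, .data$speed)) +
    ggplot2::geom_violin(fill = "grey85") +
    ggplot2::geom_jitter(width = 0.1, alpha = 0.4, size = 0.8) +
    ggplot2::stat_summary(fun = stats::median, geom = "crossbar",
                          width = 0.4, colour = "red") +
    ggplot2::labs(x = NULL, y = expression("speed (" * mu * "m/min)")) +
    ggplot2::theme_minimal()
}
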