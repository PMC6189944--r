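# Summary plots for the evaluation experiments (ggplot2, if available).

need_ggplot <- function() {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("package `ggplot2` is required for plotting")
}

#' Plot mean search time against magnification ratio
#'
#' @param search Result of [run_search_time()].
#' @return A ggplot object.
#' @export
plot_search_time <- function(search) {
  need_ggplot()
  tab <- search$table
  ggplot2::ggplot(tab, ggplot2::aes(x = factor(ratio), y = mean_s)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = mean_s - sd_s,
                                        ymax = mean_s + sd_s),
                           width = 0.2) +
    ggplot2::labs(x = "magnification ratio", y = "mean search time (s)")
}

#' Plot tracking error against target velocity
#'
#' @param sweep Result of [run_velocity_sweep()].
#' @return A ggplot object.
#' @export
plot_velocity_sweep <- function(sweep) {
  need_ggplot()
  ggplot2::ggplot(sweep, ggplot2::aes(x = velocity_mm_s,
                                      y = mean_error_um,
                                      colour = factor(ratio),
                                      linetype = roi)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = mean_error_um - sd_error_um,
                                        ymax = mean_error_um + sd_error_um),
                           width = 0.3) +
    ggplot2::labs(x = "target velocity (mm/s)", y = "mean tracking error (um)",
                  colour = "ratio", linetype = "ROI")
}

#' Plot tracking time against noise density
#'
#' @param noise Result of [run_noise_robustness()].
#' @return A ggplot object.
#' @export
plot_noise_robustness <- function(noise) {
  need_ggplot()
  ggplot2::ggplot(noise$table, ggplot2::aes(x = noise_count,
                                            y = mean_time_s,
                                            colour = method)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_colour_manual(values = c(full = "red", roi = "darkgreen")) +
    ggplot2::labs(x = "noise circles per frame", y = "mean tracking time (s)")
}

utils::globalVariables(c("ratio", "mean_s", "sd_s", "velocity_mm_s",
                         "mean_error_um", "sd_error_um", "roi",
                         "noise_count", "mean_time_s", "method"))
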