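#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_path
#'   labs facet_wrap theme_minimal coord_equal scale_color_viridis_c
NULL

#' Plot a single-cell simulation
#'
#' @param object a `pig_cell_sim` tibble.
#' @param what column to plot against time (default `"v"`).
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot pig_cell_sim
#' @export
autoplot.pig_cell_sim <- function(object, what = "v", ...) {
  ggplot(object, aes(x = .data$time, y = .data[[what]])) +
    geom_line() +
    labs(x = "time (ms)",
         y = if (what == "v") "membrane potential (mV)" else what) +
    theme_minimal()
}

#' Plot an IV curve
#'
#' @param object a `pig_iv_curve` from [run_voltage_clamp()].
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot pig_iv_curve
#' @export
autoplot.pig_iv_curve <- function(object, ...) {
  pr <- attr(object, "protocol")
  ggplot(object, aes(x = .data$v_test, y = .data$current)) +
    geom_line() + geom_point() +
    labs(x = "test potential (mV)",
         y = sprintf("%s (pA/pF, %s)", pr$measured_current,
                     pr$measurement_rule)) +
    theme_minimal()
}

#' Plot restitution curves
#'
#' @param object a `pig_restitution` from [run_restitution()].
#' @param features columns to facet over.
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot pig_restitution
#' @export
autoplot.pig_restitution <- function(object,
                                     features = c("apd_20", "apd_50",
                                                  "apd_90", "apa"),
                                     ...) {
  long <- tidyr::pivot_longer(as_tibble(object), dplyr::all_of(features),
                              names_to = "feature")
  ggplot(long, aes(x = .data$cl, y = .data$value)) +
    geom_line() + geom_point() +
    facet_wrap(~feature, scales = "free_y") +
    labs(x = "cycle length (ms)", y = NULL) +
    theme_minimal()
}

#' Plot a spiral-tip trajectory
#'
#' @param object a `tip_trajectory`.
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot tip_trajectory
#' @export
autoplot.tip_trajectory <- function(object, ...) {
  ggplot(object, aes(x = .data$x, y = .data$y, color = .data$time)) +
    geom_path() +
    coord_equal() +
    scale_color_viridis_c(name = "time (ms)") +
    labs(x = "x (cm)", y = "y (cm)") +
    theme_minimal()
}

#' Plot a signed-frequency tip spectrum
#'
#' @param object a `tip_spectrum`.
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot tip_spectrum
#' @export
autoplot.tip_spectrum <- function(object, ...) {
  peaks <- attr(object, "peaks")
  p <- ggplot(object, aes(x = .data$frequency, y = .data$magnitude)) +
    geom_line() +
    labs(x = "signed frequency (Hz)", y = "|DFT| (cm)") +
    theme_minimal()
  if (!is.null(peaks) && nrow(peaks) > 0)
    p <- p + geom_point(data = peaks, color = "red")
  p
}

#' Pseudocolour plot of one voltage snapshot
#'
#' @param sim a `pig_tissue_sim`.
#' @param frame snapshot index (default last).
#' @return A ggplot.
#' @export
plot_snapshot <- function(sim, frame = length(sim$snapshots)) {
  v <- sim$snapshots[[frame]]
  df <- expand.grid(x = (seq_len(sim$nx) - 1) * sim$dx,
                    y = (seq_len(sim$ny) - 1) * sim$dx)
  df$v <- as.vector(v)
  ggplot(df, aes(x = .data$x, y = .data$y, fill = .data$v)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "V (mV)") +
    coord_equal() +
    labs(x = "x (cm)", y = "y (cm)",
         title = sprintf("t = %.0f ms", sim$snap_times[frame])) +
    theme_minimal()
}
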