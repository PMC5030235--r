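#' Plot methods
#'
#' `autoplot()` methods give quick-look ggplots for each result type: spike
#' raster for `spike_record`, rate-vs-rank curve for `rate_profile`
#' (optionally overlaid with the stationary mean-field prediction),
#' predicted rate curve for `smf_solution`, the return-map point cloud for
#' `isi_embedding`, and the box-count scaling line for `boxcount_fit`.
#'
#' @param object The object to plot.
#' @param ... Unused.
#' @name spikedrift-autoplot
NULL

#' @rdname spikedrift-autoplot
#' @param max_points Subsample cap for large spike rasters.
#' @export
autoplot.spike_record <- function(object, max_points = 2e5, ...) {
  df <- object
  if (nrow(df) > max_points) {
    df <- df[sort(sample.int(nrow(df), max_points)), ]
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_ms, y = .data$neuron_id)) +
    ggplot2::geom_point(shape = ".", alpha = 0.6) +
    ggplot2::labs(x = "time (ms)", y = "neuron", title = "Spike raster")
}

#' @rdname spikedrift-autoplot
#' @param smf Optional `smf_solution` to overlay as a dashed curve.
#' @export
autoplot.rate_profile <- function(object, smf = NULL, ...) {
  p <- ggplot2::ggplot(object,
                       ggplot2::aes(x = .data$k_rank, y = .data$rate_hz)) +
    ggplot2::geom_line(colour = "red") +
    ggplot2::labs(x = expression(K[rank]), y = "rate (Hz)")
  if (!is.null(smf)) {
    p <- p + ggplot2::geom_line(
      data = smf$neurons,
      ggplot2::aes(x = .data$k_rank, y = .data$rate_hz),
      linetype = "dashed", colour = "black")
  }
  p
}

#' @rdname spikedrift-autoplot
#' @export
autoplot.smf_solution <- function(object, ...) {
  ggplot2::ggplot(object$neurons,
                  ggplot2::aes(x = .data$k_rank, y = .data$rate_hz)) +
    ggplot2::geom_line(linetype = "dashed") +
    ggplot2::labs(x = expression(K[rank]), y = "predicted rate (Hz)",
                  title = sprintf("Stationary mean field: r = %.1f Hz",
                                  object$r_bar_hz))
}

#' @rdname spikedrift-autoplot
#' @export
autoplot.isi_embedding <- function(object, max_points = 2e5, ...) {
  df <- object
  if (nrow(df) > max_points) {
    df <- df[sort(sample.int(nrow(df), max_points)), ]
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$s_n, y = .data$s_np1)) +
    ggplot2::geom_point(size = 0.2, alpha = 0.4, colour = "red") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "s(n) (ms)", y = "s(n+1) (ms)",
                  title = "Consecutive-ISI return map")
}

#' @rdname spikedrift-autoplot
#' @export
autoplot.boxcount_fit <- function(object, ...) {
  cv <- object$curve
  fit <- cv[cv$in_fit, ]
  ggplot2::ggplot(cv, ggplot2::aes(x = .data$r, y = .data$log2_n_box)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(data = fit, method = "lm", formula = y ~ x,
                         se = FALSE, linewidth = 0.5) +
    ggplot2::geom_hline(yintercept = log2(object$n_points),
                        linetype = "dotted") +
    ggplot2::labs(x = "grid exponent r", y = expression(log[2](N[box])),
                  title = sprintf("Box counting: D_F = %.2f", object$d_f))
}

#' Tile plot of a phase-diagram scan
#'
#' @param scan Result of [scan_phase_diagram()].
#' @param fill `"label"` (state taxonomy) or `"rate"` (mean network rate).
#' @return A ggplot.
#' @export
plot_phase_diagram <- function(scan, fill = c("label", "rate")) {
  fill <- match.arg(fill)
  p <- ggplot2::ggplot(scan,
                       ggplot2::aes(x = .data$k_mean,
                                    y = .data$delta_k / .data$k_mean))
  if (fill == "label") {
    p <- p + ggplot2::geom_tile(ggplot2::aes(fill = .data$label))
  } else {
    p <- p + ggplot2::geom_tile(ggplot2::aes(fill = .data$mean_rate_hz)) +
      ggplot2::scale_fill_viridis_c(name = "rate (Hz)")
  }
  p + ggplot2::labs(x = expression(bar(K)), y = expression(Delta * K / bar(K)))
}
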