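# ggplot2 visualizations for the main result types.  ggplot2 is a suggested
# dependency; these helpers error informatively when it is absent.

.need_ggplot <- function() {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("install ggplot2 to use the plotting helpers", call. = FALSE)
}

#' Plot a phasor histogram
#'
#' Log-scaled raster of the 2D (G, S) histogram with the universal
#' semicircle overlaid.
#'
#' @param object A [phasor_histogram()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.phasor_histogram <- function(object, ...) {
  .need_ggplot()
  df <- expand.grid(G = object$g_centers, S = object$s_centers)
  df$count <- as.vector(object$counts)
  semi <- data.frame(G = 0.5 + 0.5 * cos(seq(0, pi, length.out = 181)),
                     S = 0.5 * sin(seq(0, pi, length.out = 181)))
  ggplot2::ggplot(df[df$count > 0, ], ggplot2::aes(x = G, y = S)) +
    ggplot2::geom_raster(ggplot2::aes(fill = log10(count))) +
    ggplot2::geom_path(data = semi, linetype = 2, linewidth = 0.3,
                       colour = "grey40") +
    ggplot2::scale_fill_viridis_c(name = "log10 count") +
    ggplot2::coord_fixed(xlim = range(object$g_edges),
                         ylim = range(object$s_edges)) +
    ggplot2::theme_minimal()
}

#' Plot per-pixel fidelity maps
#'
#' @param object A [pixel_snr_mse()] result.
#' @param which `"snr"` or `"mse"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.fidelity_maps <- function(object, which = c("snr", "mse"), ...) {
  .need_ggplot()
  which <- match.arg(which)
  m <- if (which == "snr") object$snr_db else object$mse
  df <- expand.grid(row = seq_len(nrow(m)), col = seq_len(ncol(m)))
  df$value <- as.vector(m)
  ggplot2::ggplot(df, ggplot2::aes(x = col, y = row, fill = value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(
      name = if (which == "snr") "SNR (dB)" else "MSE") +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
}

#' Plot a photon-count sweep
#'
#' SNR and MSE improvement ratios versus photon-count level, one line per
#' seed.
#'
#' @param object Tibble from [run_count_sweep()].
#' @param metric `"snr_ratio"` or `"mse_ratio"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_sweep <- function(object, metric = c("snr_ratio", "mse_ratio"), ...) {
  .need_ggplot()
  metric <- match.arg(metric)
  ggplot2::ggplot(object, ggplot2::aes(x = count_level,
                                       y = .data[[metric]],
                                       group = factor(seed))) +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "photon-count level",
                  y = if (metric == "snr_ratio") "SNR ratio (dB)"
                      else "MSE ratio") +
    ggplot2::theme_minimal()
}
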