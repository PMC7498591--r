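# ggplot2 autoplot methods for the package's result types.

# Percentile stretch used for display only; quantitative operations always
# consume raw counts.
stretch01 <- function(m, lo = 0.005, hi = 0.995) {
  q <- stats::quantile(m, c(lo, hi), names = FALSE)
  if (q[2L] <= q[1L]) q[2L] <- q[1L] + 1
  pmin(pmax((m - q[1L]) / (q[2L] - q[1L]), 0), 1)
}

#' Plot a kymograph
#'
#' Displays the kymograph with a 0.5-99.5% percentile stretch (display
#' only; the underlying data stay raw counts).
#'
#' @param object A `kymograph`.
#' @param ... Unused.
#' @export
autoplot.kymograph <- function(object, ...) {
  m <- stretch01(object$data)
  df <- tidyr::expand_grid(
    row = seq_len(nrow(m)) - 1L,
    frame = seq_len(ncol(m)) - 1L
  )
  df$value <- as.vector(t(m))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$frame / object$frame_rate,
                                   y = .data$row, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white", guide = "none") +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "time (s)", y = "transverse position (px)",
                  title = sprintf("Kymograph, column %d", object$column_index)) +
    ggplot2::theme_minimal()
}

#' Plot an electropherogram
#'
#' @param object An `electropherogram`.
#' @param ... Unused.
#' @export
autoplot.electropherogram <- function(object, ...) {
  df <- object$bins
  ggplot2::ggplot(df, ggplot2::aes(x = (.data$bin_start_s + .data$bin_end_s) / 2,
                                   y = .data$count)) +
    ggplot2::geom_col(width = object$bin_width_s, fill = "steelblue") +
    ggplot2::labs(x = "migration time (s)", y = "molecules per bin") +
    ggplot2::theme_minimal()
}

#' Plot a stacking trace
#'
#' Mean band position and band width (sigma) against time, the standard
#' visual of plug self-stacking at the gel interface.
#'
#' @param object A `stacking_trace`.
#' @param ... Unused.
#' @export
autoplot.stacking_trace <- function(object, ...) {
  df <- object$fits |>
    filter(.data$valid) |>
    select("time_s", "mean_um", "sigma_um") |>
    tidyr::pivot_longer(c("mean_um", "sigma_um"),
                        names_to = "quantity", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(.data$time_s, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~quantity, scales = "free_y",
                        labeller = ggplot2::as_labeller(c(
                          mean_um = "band mean (um)",
                          sigma_um = "band sigma (um)"
                        ))) +
    ggplot2::labs(x = "time (s)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a molecular-weight calibration
#'
#' Semi-log plot of labeled molecular weight against mobility with the
#' fitted decaying exponential.
#'
#' @param object An `mw_calibration`.
#' @param ... Unused.
#' @export
autoplot.mw_calibration <- function(object, ...) {
  pts <- object$points
  grid <- tibble(mobility = seq(min(pts$mobility), max(pts$mobility),
                                length.out = 100))
  grid$mass_kda <- predict_mass(grid$mobility, object)
  ggplot2::ggplot(pts, ggplot2::aes(.data$mobility, .data$mass_kda)) +
    ggplot2::geom_line(data = grid, colour = "grey40") +
    ggplot2::geom_point(colour = "firebrick") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "mobility (m^2 V^-1 s^-1)", y = "molecular weight (kDa)",
                  title = sprintf("MW = %.3g exp(-%.3g mu)",
                                  object$A_kda, object$k)) +
    ggplot2::theme_minimal()
}

#' Plot in-gel and post-gel velocity populations
#'
#' @param object A `velocity_populations`.
#' @param ... Unused.
#' @export
autoplot.velocity_populations <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$population, .data$mean)) +
    ggplot2::geom_col(fill = "steelblue", width = 0.6) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sem,
                                        ymax = .data$mean + .data$sem),
                           width = 0.2) +
    ggplot2::labs(x = NULL, y = "velocity (um/s)",
                  title = sprintf("%.3g-fold acceleration on gel exit",
                                  object$fold_change)) +
    ggplot2::theme_minimal()
}
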