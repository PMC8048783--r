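#' Plot shortest-distance traces
#'
#' Line plot of per-frame minimum H...O distances (one line per site), as
#' produced by [min_distance_trace()].  The NAC distance threshold is drawn
#' when supplied.
#'
#' @param trace Tibble from [min_distance_trace()] (rows from several sites
#'   may be bound together).
#' @param d_max Optional distance threshold to draw, Angstrom.
#' @return A ggplot object.
#' @export
plot_distance_trace <- function(trace, d_max = NULL) {
  xvar <- if ("time_ps" %in% names(trace)) "time_ps" else "frame"
  p <- ggplot2::ggplot(trace, ggplot2::aes(
    x = .data[[xvar]], y = .data$distance,
    colour = if ("site" %in% names(trace)) .data$site else NULL)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = if (xvar == "time_ps") "time (ps)" else "frame",
                  y = "shortest H···O distance (Å)",
                  colour = "site") +
    ggplot2::theme_minimal()
  if (!is.null(d_max)) {
    p <- p + ggplot2::geom_hline(yintercept = d_max, linetype = "dashed")
  }
  p
}

#' Plot a nearest-water trace
#'
#' @param trace Tibble from [nearest_water_trace()].
#' @return A ggplot object with hydrogen-bonded frames highlighted.
#' @export
plot_water_trace <- function(trace) {
  xvar <- if ("time_ps" %in% names(trace)) "time_ps" else "frame"
  ggplot2::ggplot(trace, ggplot2::aes(x = .data[[xvar]],
                                      y = .data$distance)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point(data = trace[trace$hbond, , drop = FALSE],
                        colour = "red", size = 0.8) +
    ggplot2::labs(x = if (xvar == "time_ps") "time (ps)" else "frame",
                  y = "nearest water O···ferryl O (Å)") +
    ggplot2::theme_minimal()
}

#' Plot a tight-binding fit
#'
#' Averaged titration points with the fitted Morrison curve.
#'
#' @param object A `binding_fit` from [fit_tight_binding()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot binding_fit
#' @export
autoplot.binding_fit <- function(object, ...) {
  d <- object$data
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$ligand_uM,
                                       y = .data$deltaA)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "total ligand (µM)",
                  y = expression(Delta * A ~ "(AU)")) +
    ggplot2::theme_minimal()
  if (object$status != "no_shift" && is.finite(object$kd_nM)) {
    grid <- tibble::tibble(ligand_uM = seq(0, max(d$ligand_uM), length.out = 200))
    grid$deltaA <- tight_binding_model(grid$ligand_uM,
                                       object$enzyme_total_uM,
                                       object$kd_nM / 1000,
                                       object$delta_A_max)
    p <- p + ggplot2::geom_line(data = grid, colour = "steelblue")
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a time course with the maximal-rate window
#'
#' @param tc Time-course tibble (`time_min`, `substrate_uM`).
#' @param result Optional `kinetics_result` from [ton_from_timecourse()];
#'   shades its window.
#' @return A ggplot object.
#' @export
plot_timecourse <- function(tc, result = NULL) {
  p <- ggplot2::ggplot(tc, ggplot2::aes(x = .data$time_min,
                                        y = .data$substrate_uM)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "time (min)", y = "substrate (µM)") +
    ggplot2::theme_minimal()
  if (!is.null(result)) {
    p <- p + ggplot2::annotate("rect", xmin = result$window[[1]],
                               xmax = result$window[[2]], ymin = -Inf,
                               ymax = Inf, alpha = 0.15, fill = "steelblue")
  }
  p
}

#' Plot a mobility (RMSF) profile
#'
#' @param profile Tibble from [rmsf()].
#' @return A ggplot bar chart of per-atom RMSF.
#' @export
plot_rmsf <- function(profile) {
  ggplot2::ggplot(profile, ggplot2::aes(x = factor(.data$index),
                                        y = .data$rmsf)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "roster index", y = "RMSF (Å)") +
    ggplot2::theme_minimal()
}
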