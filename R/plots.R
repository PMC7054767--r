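# ggplot2 autoplot methods for the result types, and broom-style
# tidy()/glance() for simulation series.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a simulation result series
#'
#' Long format: one row per (time step, signal) with columns `t`, `cycle`,
#' `signal`, `value`.
#'
#' @param x A `result_series`.
#' @param ... Unused.
#' @export
tidy.result_series <- function(x, ...) {
  df <- tibble::as_tibble(as.data.frame(x))
  tidyr_cols <- setdiff(names(df), c("step", "t", "cycle"))
  out <- do.call(rbind, lapply(tidyr_cols, function(cn) {
    tibble::tibble(t = df$t, cycle = df$cycle, signal = cn, value = df[[cn]])
  }))
  tibble::as_tibble(out)
}

#' One-row summary of a simulation result series
#'
#' Final-cycle means of the probe pressures and fluxes, the relative mass
#' defect, and the mesh/provenance identifiers.
#'
#' @param x A `result_series`.
#' @param ... Unused.
#' @export
glance.result_series <- function(x, ...) {
  df <- as.data.frame(x)
  last <- df[df$cycle == max(df$cycle), ]
  qout <- grep("^Q_out_", names(df), value = TRUE)
  mass <- abs(last$Q_in + rowSums(last[, qout, drop = FALSE]))
  ms <- attr(x, "mesh_stats")
  tibble::tibble(
    n_steps = nrow(df),
    n_cycles = max(df$cycle),
    Pa_mean_last = mean(last$Pa),
    Q_in_mean_last = mean(last$Q_in),
    mass_defect_rel = max(mass / pmax(abs(last$Q_in), 1e-12)),
    nv = ms$nv, nt = ms$nt, h = ms$h,
    config_hash = attr(x, "provenance")$config_hash)
}

#' Plot probe-pressure and flux traces
#'
#' @param object A `result_series`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.result_series <- function(object, ...) {
  long <- tidy(object)
  keep <- grepl("^(Pa$|Pdistal_)", long$signal)
  ggplot2::ggplot(long[keep, ],
                  ggplot2::aes(x = .data$t, y = .data$value,
                               colour = .data$signal)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "t (s)", y = "pressure (mmHg)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot per-cycle FFR and its running average
#'
#' @param object An `ffr_record`.
#' @param cutoffs Clinical cutoffs drawn as reference lines.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ffr_record <- function(object, cutoffs = c(0.75, 0.80), ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cycle)) +
    ggplot2::annotate("rect", xmin = -Inf, xmax = Inf,
                      ymin = cutoffs[1], ymax = cutoffs[length(cutoffs)],
                      alpha = 0.15, fill = "grey40") +
    ggplot2::geom_line(ggplot2::aes(y = .data$FFR), linetype = 2) +
    ggplot2::geom_point(ggplot2::aes(y = .data$FFR)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$FFR_a), colour = "red") +
    ggplot2::geom_point(ggplot2::aes(y = .data$FFR_a), colour = "red") +
    ggplot2::labs(x = "cardiac cycle", y = "FFR (points) / FFR_a (red)") +
    ggplot2::theme_minimal()
}

#' Plot an FFR mesh-convergence study
#'
#' Final-cycle running-average FFR against mesh vertex count.
#'
#' @param object An `ffr_convergence` table.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ffr_convergence <- function(object, ...) {
  df <- as.data.frame(object)
  ffa <- grep("^FFRa_c", names(df), value = TRUE)
  df$FFR_a_final <- df[[ffa[length(ffa)]]]
  ggplot2::ggplot(df[df$ok, ],
                  ggplot2::aes(x = .data$nv, y = .data$FFR_a_final)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "mesh vertices", y = "FFR_a (final cycle)") +
    ggplot2::theme_minimal()
}

#' Plot a sensor-displacement sweep
#'
#' FFR against sensor offset (in units of the reference diameter), with
#' the classification cutoff band.
#'
#' @param object An `ffr_sweep` table.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ffr_sweep <- function(object, ...) {
  cutoff <- attr(object, "cutoff")
  df <- as.data.frame(object)
  ggplot2::ggplot(df[df$ok, ],
                  ggplot2::aes(x = .data$offset_Dref, y = .data$FFR_a)) +
    ggplot2::annotate("rect", xmin = -Inf, xmax = Inf,
                      ymin = cutoff - 0.005, ymax = cutoff + 0.005,
                      alpha = 0.3, fill = "grey40") +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(colour = .data$class)) +
    ggplot2::labs(x = paste0("sensor offset (x D_ref, ",
                             attr(object, "direction"), ")"),
                  y = "FFR_a", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a meshed domain
#'
#' Boundary edges coloured by tag (inlet, outlets, walls, sensor
#' contours).
#'
#' @param object A `mesh_domain`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mesh_domain <- function(object, ...) {
  b <- object$boundary
  df <- data.frame(
    x = object$vertices[b$v1, 1], y = object$vertices[b$v1, 2],
    xend = object$vertices[b$v2, 1], yend = object$vertices[b$v2, 2],
    tag = sub("_[0-9]+$", "", b$tag))
  ggplot2::ggplot(df,
                  ggplot2::aes(x = .data$x, y = .data$y,
                               xend = .data$xend, yend = .data$yend,
                               colour = .data$tag)) +
    ggplot2::geom_segment() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (cm)", y = "y (cm)", colour = NULL) +
    ggplot2::theme_minimal()
}
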