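# Virtual FFR estimation mimicking the clinical pressure-wire device:
# cycle-wise temporal means of the aortic-box and sensor-contour pressures,
# their ratio per cycle, and the running average across cycles.

#' Aortic sampling-box specification
#'
#' The aortic pressure is sampled as the arithmetic mean of nodal pressures
#' inside a virtual (non-obstacle) band of the inlet branch centred at a
#' prescribed arclength — 1 cm from the inlet by default, past entrance
#' transients and upstream of the first lesion.
#'
#' @param arclength Band centre along the inlet branch, cm.
#' @param half_width Band half-width, cm.
#' @return An object of class `probe_spec`.
#' @export
probe_spec <- function(arclength = 1, half_width = 0.05) {
  stopifnot(arclength > 0, half_width > 0)
  structure(list(arclength = arclength, half_width = half_width),
            class = "probe_spec")
}

#' Vertices inside the aortic sampling box
#'
#' @param m A `mesh_domain` with vertex metadata.
#' @param probe A [probe_spec()].
#' @return Integer vertex indices.
#' @export
aortic_box_vertices <- function(m, probe = probe_spec()) {
  stopifnot(inherits(m, "mesh_domain"))
  meta <- m$vertex_meta
  if (is.null(meta)) stop("mesh carries no vertex metadata for probes")
  inlet_v <- unique(as.integer(unlist(
    m$boundary[m$boundary$tag == "inlet", c("v1", "v2")])))
  root <- as.integer(names(which.max(table(meta$branch[inlet_v]))))
  idx <- which(meta$branch == root &
                 abs(meta$s - probe$arclength) <= probe$half_width)
  if (length(idx) == 0L) {
    stop("empty aortic box: no mesh vertices within ", probe$half_width,
         " cm of arclength ", probe$arclength)
  }
  idx
}

#' Mean aortic-box pressure
#'
#' Arithmetic mean of the nodal pressures inside the virtual aortic box
#' (the box is not an obstacle; nothing is meshed away).
#'
#' @param m A `mesh_domain`.
#' @param p Nodal pressures, mmHg (vertex order), or a `flow_state` (Pa,
#'   converted internally).
#' @param probe A [probe_spec()].
#' @return Mean pressure, mmHg.
#' @export
sample_aortic <- function(m, p, probe = probe_spec()) {
  if (inherits(p, "flow_state")) p <- pa_to_mmhg(p$p)
  mean(p[aortic_box_vertices(m, probe)])
}

#' Mean sensor-contour pressure
#'
#' Arithmetic mean of the nodal pressures over the boundary vertices of one
#' sensor hole.
#'
#' @param m A `mesh_domain`.
#' @param p Nodal pressures, mmHg, or a `flow_state`.
#' @param sensor_tag Tag of the sensor contour, e.g. `"sensor_1"`.
#' @return Mean pressure, mmHg.
#' @export
sample_distal <- function(m, p, sensor_tag = "sensor_1") {
  if (inherits(p, "flow_state")) p <- pa_to_mmhg(p$p)
  sel <- m$boundary$tag == sensor_tag
  if (!any(sel)) stop("no boundary with tag ", sensor_tag)
  idx <- sort(unique(as.integer(unlist(m$boundary[sel, c("v1", "v2")]))))
  mean(p[idx])
}

#' Temporal mean of a sampled trace over one cardiac cycle
#'
#' `(1/Tc) * int p dt` over cycle `cycle_k`, by left-rectangle quadrature
#' on the sampling grid — mirroring a device that averages the samples
#' captured at each acquisition tick. Trapezoid quadrature is available
#' for comparison and differs by O(dt).
#'
#' @param trace Sampled values at times `dt, 2 dt, ...` (step-end
#'   convention of the solver).
#' @param cycle_k Cycle number (1-based).
#' @param Tc Cycle duration, s.
#' @param dt Sampling interval, s.
#' @param method `"rectangle"` or `"trapezoid"`.
#' @return The cycle mean.
#' @export
cycle_mean <- function(trace, cycle_k, Tc, dt,
                       method = c("rectangle", "trapezoid")) {
  method <- match.arg(method)
  spc <- round(Tc / dt)
  if (abs(Tc / dt - spc) > 1e-9) stop("Tc / dt must be an integer")
  i1 <- (cycle_k - 1L) * spc + 1L
  i2 <- cycle_k * spc
  if (i1 < 1L || i2 > length(trace)) {
    stop("trace does not cover cycle ", cycle_k)
  }
  x <- trace[i1:i2]
  if (method == "rectangle") {
    mean(x)
  } else {
    x0 <- if (i1 == 1L) x[1L] else trace[i1 - 1L]
    (sum(x) + (x0 - x[spc]) / 2) / spc
  }
}

#' Per-cycle FFR and running average
#'
#' For each cardiac cycle `k`, computes the temporal means of the aortic
#' and distal pressure traces, their ratio `FFR_k`, the running average
#' `FFR_a(k) = mean(FFR_1, ..., FFR_k)`, and the clinical classification of
#' `FFR_a`.
#'
#' @param Pa_trace Aortic-box pressure samples, mmHg (length
#'   `n_cycles * Tc / dt`).
#' @param Pdistal_trace Sensor-contour pressure samples, mmHg.
#' @param n_cycles Number of cycles covered.
#' @param Tc Cycle duration, s.
#' @param dt Sampling interval, s.
#' @param method Quadrature for the cycle means (see [cycle_mean()]).
#' @return An `ffr_record` tibble with columns `cycle`, `Pa_mean`,
#'   `Pdistal_mean`, `FFR`, `FFR_a`, `class`.
#' @export
compute_ffr <- function(Pa_trace, Pdistal_trace, n_cycles, Tc, dt,
                        method = "rectangle") {
  spc <- round(Tc / dt)
  stopifnot(length(Pa_trace) >= n_cycles * spc,
            length(Pdistal_trace) == length(Pa_trace))
  Pa_m <- vapply(seq_len(n_cycles), cycle_mean, numeric(1),
                 trace = Pa_trace, Tc = Tc, dt = dt, method = method)
  Pd_m <- vapply(seq_len(n_cycles), cycle_mean, numeric(1),
                 trace = Pdistal_trace, Tc = Tc, dt = dt, method = method)
  if (any(Pa_m <= 0)) stop("nonpositive mean aortic pressure")
  ffr <- Pd_m / Pa_m
  ffr_a <- cumsum(ffr) / seq_len(n_cycles)
  rec <- tibble::tibble(
    cycle = seq_len(n_cycles),
    Pa_mean = Pa_m,
    Pdistal_mean = Pd_m,
    FFR = ffr,
    FFR_a = ffr_a,
    class = classify_ffr(ffr_a))
  class(rec) <- c("ffr_record", class(rec))
  rec
}

#' FFR records of a simulation
#'
#' Convenience wrapper: extracts the aortic and per-sensor distal traces of
#' a [run_simulation()] result and returns one `ffr_record` per sensor.
#'
#' @param res A `result_series`.
#' @param method Quadrature for the cycle means.
#' @return Named list of `ffr_record` tibbles (`sensor_1`, ...).
#' @export
ffr_from_series <- function(res, method = "rectangle") {
  cfg <- attr(res, "config")
  sens <- grep("^Pdistal_", names(res), value = TRUE)
  if (length(sens) == 0L) stop("result has no distal sensor traces")
  out <- lapply(sens, function(cn) {
    compute_ffr(res$Pa, res[[cn]], cfg$n_cycles, cfg$Tc, cfg$dt,
                method = method)
  })
  names(out) <- sub("Pdistal", "sensor", sens)
  out
}

#' Clinical FFR classification
#'
#' Two-cutoff mode (default): below 0.75 the lesion is haemodynamically
#' `significant`, above 0.80 `nonsignificant`, between them `gray_zone`.
#' Single-cutoff mode uses 0.75 alone (significant vs nonsignificant), as
#' in sensor-position sweeps.
#'
#' @param ffr_value FFR value(s), `> 0`.
#' @param cutoffs Length-2 numeric `(lower, upper)` or a single cutoff.
#' @return Factor with levels `significant`, `gray_zone`, `nonsignificant`.
#' @export
classify_ffr <- function(ffr_value, cutoffs = c(0.75, 0.80)) {
  stopifnot(all(ffr_value > 0))
  lv <- c("significant", "gray_zone", "nonsignificant")
  if (length(cutoffs) == 1L) {
    out <- ifelse(ffr_value < cutoffs, "significant", "nonsignificant")
  } else {
    stopifnot(cutoffs[1] <= cutoffs[2])
    out <- ifelse(ffr_value < cutoffs[1], "significant",
                  ifelse(ffr_value > cutoffs[2], "nonsignificant",
                         "gray_zone"))
  }
  factor(out, levels = lv)
}

#' Tidy an FFR record
#'
#' Returns the per-cycle table (cycle, mean pressures, FFR, running
#' average, classification) as a plain tibble.
#'
#' @param x An `ffr_record`.
#' @param ... Unused.
#' @export
tidy.ffr_record <- function(x, ...) {
  tibble::as_tibble(unclass(x)[c("cycle", "Pa_mean", "Pdistal_mean",
                                 "FFR", "FFR_a", "class")])
}

#' One-row summary of an FFR record
#'
#' The final running-average FFR, its classification, and whether the
#' running average was stable to two decimals from the third cycle on.
#'
#' @param x An `ffr_record`.
#' @param ... Unused.
#' @export
glance.ffr_record <- function(x, ...) {
  n <- nrow(x)
  tibble::tibble(
    n_cycles = n,
    FFR_a = x$FFR_a[n],
    class = x$class[n],
    stable_2dp = if (n >= 3L) {
      all(abs(round(x$FFR_a[3:n], 2) - round(x$FFR_a[n], 2)) < 1e-12)
    } else NA)
}
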