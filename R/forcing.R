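#' Pulsatile inlet waveform
#'
#' Piecewise-sinusoidal left-coronary inlet speed over one cardiac cycle of
#' period `Tc`:
#' \deqn{I(t) = I_p + I_0 \sin(\pi (t - t_s)/T_{sys})} during systole and
#' \deqn{I(t) = I_p + I_c \sin(\pi (t - t_d)/(T_c - T_{sys}))} during
#' diastole, clipped below at zero and extended periodically. With the
#' defaults the waveform is continuous at the phase change (both one-sided
#' limits equal `Ip`) and the clip never activates.
#'
#' @param Ip Dominant (baseline) speed, cm/s.
#' @param I0 Systolic amplitude, cm/s.
#' @param Ic Diastolic amplitude, cm/s.
#' @param Tsys Systole duration, s.
#' @param Tc Cardiac-cycle duration, s.
#' @param ts Systole start within the cycle, s.
#' @param td Diastole start within the cycle, s.
#' @return An object of class `inlet_waveform`.
#' @export
inlet_waveform <- function(Ip = 10, I0 = 10, Ic = 10, Tsys = 0.33, Tc = 0.8,
                           ts = 0, td = Tsys) {
  stopifnot(Tsys > 0, Tc > Tsys, Ip >= 0, I0 >= 0, Ic >= 0)
  structure(list(Ip = Ip, I0 = I0, Ic = Ic, Tsys = Tsys, Tc = Tc,
                 ts = ts, td = td),
            class = "inlet_waveform")
}

#' Inlet speed at time t
#'
#' @param t Time(s), s; `t >= 0`. Vectorized.
#' @param wf An [inlet_waveform()] object.
#' @return Inlet speed(s), cm/s.
#' @export
inlet_speed <- function(t, wf = inlet_waveform()) {
  stopifnot(inherits(wf, "inlet_waveform"), all(t >= 0))
  tau <- t %% wf$Tc
  sys <- tau <= wf$Tsys
  v <- numeric(length(tau))
  v[sys] <- wf$Ip + wf$I0 * sin(pi * (tau[sys] - wf$ts) / wf$Tsys)
  v[!sys] <- wf$Ip + wf$Ic * sin(pi * (tau[!sys] - wf$td) / (wf$Tc - wf$Tsys))
  pmax(v, 0)
}

#' Simplified systolic aortic inflow
#'
#' Half-sine flow pulse during systole, zero during diastole: the idealized
#' aortic flow used to construct the intramyocardial downstream pressure
#' `P_d(t)` of the Windkessel outlets.
#'
#' @param Q0 Pulse amplitude, cm^3/s.
#' @param Tsys,Tc Phase durations, s.
#' @return An object of class `aortic_flow_model`.
#' @export
aortic_flow_model <- function(Q0 = 6, Tsys = 0.33, Tc = 0.8) {
  stopifnot(Q0 >= 0, Tsys > 0, Tc > Tsys)
  structure(list(Q0 = Q0, Tsys = Tsys, Tc = Tc), class = "aortic_flow_model")
}

#' Aortic inflow at time t
#'
#' @param t Time(s), s; vectorized.
#' @param q An [aortic_flow_model()] object.
#' @return Flow(s), cm^3/s (nonnegative; exactly zero in diastole).
#' @export
aortic_inflow <- function(t, q = aortic_flow_model()) {
  stopifnot(inherits(q, "aortic_flow_model"), all(t >= 0))
  tau <- t %% q$Tc
  ifelse(tau < q$Tsys, q$Q0 * sin(pi * tau / q$Tsys), 0)
}

#' Downstream (intramyocardial) pressure P_d(t)
#'
#' Analytic periodic steady state of the 2-element Windkessel ODE
#' \deqn{Q(t) = (P - P_b)/R + C\, d(P - P_b)/dt}
#' driven by the half-sine aortic inflow of [aortic_inflow()] around a
#' constant baseline `P_b`. During systole the solution is the sinusoidal
#' particular solution plus an exponential transient; during diastole it
#' relaxes exponentially to the baseline; the cycle-start value is chosen so
#' that `P_d(t + Tc) = P_d(t)` exactly.
#'
#' @param t Time(s), s; vectorized.
#' @param wk A [windkessel_params()] object.
#' @param q An [aortic_flow_model()] object.
#' @param baseline Baseline pressure `P_b`, mmHg.
#' @return Pressure(s), mmHg.
#' @export
downstream_pressure <- function(t, wk = windkessel_params(),
                                q = aortic_flow_model(), baseline = 2) {
  stopifnot(inherits(wk, "windkessel_params"),
            inherits(q, "aortic_flow_model"), all(t >= 0))
  delta <- wk_delta(wk)
  Ts <- q$Tsys
  Tc <- q$Tc
  omega <- pi / Ts
  # particular solution A sin(wt) + B cos(wt) of C y' + y/R = Q0 sin(wt)
  A <- q$Q0 * wk$R / (1 + (delta * omega)^2)
  B <- -delta * omega * A
  a <- exp(-Ts / delta)
  b <- exp(-(Tc - Ts) / delta)
  # periodicity: y(Tc) = y(0); y_p(Ts) = -B
  y0 <- -B * b * (1 + a) / (1 - a * b)
  tau <- t %% Tc
  y <- numeric(length(tau))
  sys <- tau < Ts
  y[sys] <- A * sin(omega * tau[sys]) + B * cos(omega * tau[sys]) +
    (y0 - B) * exp(-tau[sys] / delta)
  yTs <- -B + (y0 - B) * a
  y[!sys] <- yTs * exp(-(tau[!sys] - Ts) / delta)
  baseline + y
}
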