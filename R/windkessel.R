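#' 2-element Windkessel parameters
#'
#' Peripheral resistance `R` (mmHg s/cm^3) and arterial compliance `C`
#' (cm^3/mmHg) of the lumped RC model of the downstream vascular bed,
#' related to outlet pressure `P` and flow `Q` by
#' \deqn{Q(t) = (P - P_d)/R + C\, d(P - P_d)/dt.}
#' The time constant `delta = R C` is always derived on demand via
#' [wk_delta()], never stored, so it cannot go stale.
#'
#' @param R Resistance, mmHg s/cm^3.
#' @param C Compliance, cm^3/mmHg.
#' @return An object of class `windkessel_params`.
#' @export
windkessel_params <- function(R = 0.95, C = 1.06) {
  stopifnot(is.numeric(R), is.numeric(C), length(R) == 1L, length(C) == 1L)
  if (!(R > 0) || !(C > 0)) stop("require R > 0 and C > 0")
  structure(list(R = R, C = C), class = "windkessel_params")
}

#' Windkessel time constant
#'
#' @param p A [windkessel_params()] object.
#' @return `delta = R * C` in seconds.
#' @export
wk_delta <- function(p) {
  stopifnot(inherits(p, "windkessel_params"))
  p$R * p$C
}

#' Reference integration of the Windkessel ODE
#'
#' Integrates `Q = (P - P_d)/R + C d(P - P_d)/dt` for `P(t)` on a uniform
#' time grid, treating `Q` and `P_d` as piecewise constant over each step
#' (value attached to the step being taken) and using the exact exponential
#' update for the resulting linear ODE. This is the reference against which
#' the operator-split outlet coupling is tested.
#'
#' @param Q Flow samples, cm^3/s: `Q[n]` is the flow during step `n`
#'   (constant on `((n-1) dt, n dt]`).
#' @param dt Step size, s (`> 0`).
#' @param p A [windkessel_params()] object.
#' @param P0 Initial pressure `P(0)`, mmHg.
#' @param Pd Downstream pressure, mmHg: scalar or a vector of length
#'   `length(Q) + 1` sampled at times `0, dt, ..., n dt`.
#' @return Pressures `P` at times `0, dt, ..., n dt` (length `length(Q)+1`),
#'   mmHg.
#' @export
integrate_windkessel <- function(Q, dt, p = windkessel_params(), P0 = 0,
                                 Pd = 0) {
  stopifnot(inherits(p, "windkessel_params"), is.numeric(Q))
  if (!(is.numeric(dt) && length(dt) == 1L && dt > 0)) stop("require dt > 0")
  n <- length(Q)
  if (length(Pd) == 1L) Pd <- rep(Pd, n + 1L)
  stopifnot(length(Pd) == n + 1L)
  delta <- wk_delta(p)
  e <- exp(-dt / delta)
  P <- numeric(n + 1L)
  P[1L] <- P0
  y <- P0 - Pd[1L]
  for (k in seq_len(n)) {
    y <- e * y + p$R * (1 - e) * Q[k]
    P[k + 1L] <- y + Pd[k + 1L]
  }
  P
}

#' One-step update of the exponential flow history
#'
#' Advances the exponentially weighted flow integral
#' \deqn{h(t) = \int_0^t e^{-(t - t_1)/\delta}\, Q(t_1)\, dt_1}
#' by one step of size `dt`, treating `Q` as constant (`Q_n`) over the step:
#' `h_n = e^{-dt/delta} h_{n-1} + delta (1 - e^{-dt/delta}) Q_n`. The
#' exponential-integrator increment is exact for piecewise-constant flow; a
#' trapezoid increment is available for cross-checking and differs from it
#' by O(dt^2) per step.
#'
#' @param h_prev History at the previous step, cm^3.
#' @param Q_n Flow during the step, cm^3/s.
#' @param dt Step size, s (`> 0`).
#' @param delta Time constant `R C`, s.
#' @param method `"exponential"` (exact for stepwise flow) or `"trapezoid"`.
#' @return Updated history, cm^3.
#' @export
history_update <- function(h_prev, Q_n, dt, delta,
                           method = c("exponential", "trapezoid")) {
  method <- match.arg(method)
  if (!(dt > 0)) stop("require dt > 0")
  e <- exp(-dt / delta)
  if (method == "exponential") {
    e * h_prev + delta * (1 - e) * Q_n
  } else {
    e * h_prev + dt / 2 * (e + 1) * Q_n
  }
}

# Direct (O(n^2)) evaluation of the convolution under the same quadrature,
# used as a brute-force oracle for the recursion.
history_direct <- function(Q, dt, delta,
                           method = c("exponential", "trapezoid")) {
  method <- match.arg(method)
  n <- length(Q)
  t_n <- n * dt
  e1 <- exp(-dt / delta)
  inc <- if (method == "exponential") delta * (1 - e1) else dt / 2 * (e1 + 1)
  sum(exp(-(t_n - seq_len(n) * dt) / delta) * inc * Q)
}

#' Outlet coupling state
#'
#' Per-outlet running state of the coupled Windkessel boundary condition:
#' the exponential flow history `h` (zero at `t = 0`), the latest outlet
#' pressure offset `y = P - P_d`, and the initial data `P0`, `Q_init`,
#' `Pd0` entering the relaxation term.
#'
#' @param outlet_id Outlet tag number.
#' @param P0 Initial outlet pressure, mmHg.
#' @param Q_init Initial outlet flow, cm^3/s.
#' @param Pd0 Downstream pressure at `t = 0`, mmHg.
#' @return An object of class `outlet_state`.
#' @export
outlet_state <- function(outlet_id = 1L, P0 = 0, Q_init = 0, Pd0 = 0) {
  structure(list(outlet_id = outlet_id, history = 0, y = P0 - Pd0,
                 Q_prev = Q_init, P0 = P0, Q_init = Q_init, Pd0 = Pd0,
                 t = 0, n = 0L),
            class = "outlet_state")
}

#' Implicit/explicit split of the Windkessel outlet traction
#'
#' Decomposes the outlet pressure applied as a normal traction at step `n`
#' into an implicit resistive coefficient (multiplying the instantaneous
#' outlet flux inside the linear solve) and an explicit part known from the
#' stored state:
#' `P_n = implicit_R * Q_n + explicit_traction`.
#'
#' At the initial instant (`state$n == 0`, zero accumulated history) the
#' split is `P_0 = R Q_0 + (P0 - R Q_init - Pd0) + P_d(0)`; at later steps
#' the exact exponential update of the RC equation gives
#' `implicit_R = R (1 - e^{-dt/delta})` and
#' `explicit = e^{-dt/delta} (P_{n-1} - P_d(t_{n-1})) + P_d(t_n)`. Fed with
#' piecewise-constant flow, the recombined pressures coincide with
#' [integrate_windkessel()] to machine precision. A free (traction-free)
#' outlet has both parts zero.
#'
#' @param state An [outlet_state()].
#' @param p A [windkessel_params()] object.
#' @param Pd_n Downstream pressure at the new time, mmHg.
#' @param dt Step size, s.
#' @param kind `"windkessel"` or `"free"`.
#' @return List with `implicit_R` (mmHg s/cm^3) and `explicit_traction`
#'   (mmHg).
#' @export
outlet_traction_split <- function(state, p = windkessel_params(), Pd_n = 0,
                                  dt = 5e-3, kind = c("windkessel", "free")) {
  kind <- match.arg(kind)
  if (kind == "free") return(list(implicit_R = 0, explicit_traction = 0))
  stopifnot(inherits(state, "outlet_state"), inherits(p, "windkessel_params"))
  delta <- wk_delta(p)
  if (state$n == 0L) {
    list(implicit_R = p$R,
         explicit_traction = state$P0 - p$R * state$Q_init - state$Pd0 + Pd_n)
  } else {
    e <- exp(-dt / delta)
    list(implicit_R = p$R * (1 - e),
         explicit_traction = e * state$y + Pd_n)
  }
}

#' Advance an outlet state after a solve
#'
#' Records the flux obtained from the linear solve, the resulting outlet
#' pressure, and updates the exponential history.
#'
#' @param state An [outlet_state()].
#' @param p A [windkessel_params()] object.
#' @param Q_n Outlet flux at the new time, cm^3/s.
#' @param P_n Outlet pressure applied at the new time, mmHg.
#' @param Pd_n Downstream pressure at the new time, mmHg.
#' @param dt Step size, s.
#' @return The updated `outlet_state`.
#' @export
outlet_state_advance <- function(state, p, Q_n, P_n, Pd_n, dt) {
  stopifnot(inherits(state, "outlet_state"))
  if (state$n > 0L) {
    state$history <- history_update(state$history, Q_n, dt, wk_delta(p))
    state$t <- state$t + dt
  }
  state$y <- P_n - Pd_n
  state$Q_prev <- Q_n
  state$n <- state$n + 1L
  state
}

#' Per-outlet boundary-condition assignment
#'
#' Assigns every outlet exactly one kind, `"windkessel"` or `"free"`. All
#' Windkessel outlets share a single parameter set (the model keeps
#' identical R and C on every outlet). `"mixed"` is expressed by passing a
#' `kinds` vector with one `"free"` entry, conventionally the longest
#' branch.
#'
#' @param kinds Character vector of kinds, one per outlet, in outlet-tag
#'   order.
#' @param params A [windkessel_params()] object shared by all Windkessel
#'   outlets.
#' @return An object of class `outlet_bc_assignment`.
#' @export
outlet_bc_assignment <- function(kinds, params = windkessel_params()) {
  stopifnot(is.character(kinds), length(kinds) >= 1L)
  if (!all(kinds %in% c("windkessel", "free")))
    stop("outlet kinds must be 'windkessel' or 'free'")
  stopifnot(inherits(params, "windkessel_params"))
  structure(list(kinds = kinds, params = params),
            class = "outlet_bc_assignment")
}
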