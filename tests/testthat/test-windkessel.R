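test_that("RC integration reaches the resistive steady state", {
  P <- integrate_windkessel(rep(1, 4000), dt = 0.01)
  expect_equal(tail(P, 1), 0.95, tolerance = 1e-7)
})

test_that("free decay and step response match the closed forms", {
  p <- windkessel_params()
  d <- wk_delta(p)
  expect_equal(d, 0.95 * 1.06)
  # homogeneous decay P(t) = e^(-t/delta)
  n <- 500L
  P <- integrate_windkessel(rep(0, n), dt = d / 100, p, P0 = 1)
  tt <- (0:n) * d / 100
  expect_equal(P, exp(-tt / d), tolerance = 1e-12)
  # unit step at t = delta: R (1 - e^-1)
  n <- 1000L
  P <- integrate_windkessel(rep(1, n), dt = d / n, p, P0 = 0)
  expect_equal(P[n + 1L], p$R * (1 - exp(-1)), tolerance = 1e-10)
})

test_that("exponential history obeys its recursion and oracle", {
  d <- wk_delta(windkessel_params())
  dt <- 0.005
  # pure decay
  h <- 2.5
  for (i in 1:10) h <- history_update(h, 0, dt, d)
  expect_equal(h, 2.5 * exp(-10 * dt / d), tolerance = 1e-12)
  # constant flow saturates at Q * delta
  h <- 0
  for (i in 1:20000) h <- history_update(h, 3, dt, d)
  expect_equal(h, 3 * d, tolerance = 1e-9)
  # recursion equals the direct convolution under the same quadrature
  set.seed(7)
  Q <- rnorm(300, 2, 1)
  h <- 0
  for (k in seq_along(Q)) h <- history_update(h, Q[k], dt, d)
  expect_lt(abs(h - vffr:::history_direct(Q, dt, d)) / abs(h), 1e-10)
  # trapezoid and exponential increments agree to O(dt^2)
  expect_equal(history_update(0, 1, dt, d, "trapezoid"),
               history_update(0, 1, dt, d, "exponential"),
               tolerance = dt^2)
})

test_that("traction split satisfies the initial-condition example", {
  p <- windkessel_params()
  st <- outlet_state(1, P0 = 5, Q_init = 0, Pd0 = 5)
  sp <- outlet_traction_split(st, p, Pd_n = 5, dt = 5e-3)
  expect_equal(sp$explicit_traction, 5)
  expect_equal(sp$implicit_R, p$R)
  # free outlets carry no traction
  spf <- outlet_traction_split(st, p, Pd_n = 5, dt = 5e-3, kind = "free")
  expect_identical(spf, list(implicit_R = 0, explicit_traction = 0))
})

test_that("split-and-recombine reproduces the RC equation exactly for
           stepwise flow", {
  p <- windkessel_params()
  dt <- 0.004
  set.seed(11)
  # arbitrary piecewise-constant flow sampled at the step instants
  Q <- rep(runif(12, 0, 3), each = 25)
  N <- length(Q)
  # reference: flows during the intervals between those instants
  ref <- integrate_windkessel(Q[-1], dt, p, P0 = p$R * Q[1] + 1.5, Pd = 1.5)
  st <- outlet_state(1, P0 = p$R * Q[1] + 1.5, Q_init = Q[1], Pd0 = 1.5)
  P <- numeric(N)
  for (n in seq_len(N)) {
    sp <- outlet_traction_split(st, p, Pd_n = 1.5, dt = dt)
    P[n] <- sp$implicit_R * Q[n] + sp$explicit_traction
    st <- outlet_state_advance(st, p, Q[n], P[n], 1.5, dt)
  }
  # P[n] is the outlet pressure at t = (n-1) dt
  expect_lt(max(abs(P - ref)) / max(abs(ref)), 1e-10)
})

test_that("outlet assignment validation and derived delta", {
  expect_error(outlet_bc_assignment(c("windkessel", "nope")), "kinds")
  a <- outlet_bc_assignment(c("windkessel", "free", "windkessel"))
  expect_length(a$kinds, 3L)
  p <- windkessel_params(R = 2, C = 3)
  expect_equal(wk_delta(p), 6) # recomputed from the current R, C
  expect_error(windkessel_params(R = -1), "R > 0")
})
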