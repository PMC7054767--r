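test_that("inlet waveform matches its piecewise-sinusoid definition", {
  wf <- inlet_waveform()
  expect_equal(inlet_speed(0, wf), 10)
  expect_equal(inlet_speed(0.165, wf), 20) # mid-systole: Ip + I0
  # continuity at the systole/diastole changeover
  eps <- 1e-9
  expect_equal(inlet_speed(wf$Tsys - eps, wf), 10, tolerance = 1e-6)
  expect_equal(inlet_speed(wf$Tsys + eps, wf), 10, tolerance = 1e-6)
  # periodic extension
  tt <- seq(0, 0.8, by = 0.013)
  expect_equal(inlet_speed(tt + wf$Tc, wf), inlet_speed(tt, wf))
})

test_that("inlet waveform bounds hold over the cycle", {
  wf <- inlet_waveform()
  tt <- seq(0, wf$Tc, length.out = 2000)
  v <- inlet_speed(tt, wf)
  expect_true(all(v >= 0))
  expect_equal(max(v), wf$Ip + max(wf$I0, wf$Ic), tolerance = 1e-5)
})

test_that("aortic inflow is a half-sine in systole and zero in diastole", {
  q <- aortic_flow_model(Q0 = 7)
  expect_equal(aortic_inflow(q$Tsys / 2, q), 7)
  dias <- seq(q$Tsys + 1e-6, q$Tc - 1e-6, length.out = 50)
  expect_equal(aortic_inflow(dias, q), rep(0, 50))
  q0 <- aortic_flow_model(Q0 = 0)
  expect_equal(aortic_inflow(seq(0, 1.6, by = 0.01), q0),
               rep(0, length(seq(0, 1.6, by = 0.01))))
})

test_that("downstream pressure reduces to the baseline without forcing", {
  wk <- windkessel_params()
  q0 <- aortic_flow_model(Q0 = 0)
  tt <- seq(0, 2, by = 0.01)
  expect_equal(downstream_pressure(tt, wk, q0, baseline = 6),
               rep(6, length(tt)))
})

test_that("analytic downstream pressure matches an adaptive ODE solve", {
  wk <- windkessel_params()
  q <- aortic_flow_model()
  base <- 2
  f <- function(t, y, parms) {
    list((aortic_inflow(t, q) - (y - base) / wk$R) / wk$C)
  }
  tt <- seq(0, 40 * q$Tc, by = 0.002)
  sol <- deSolve::ode(y = c(P = base), times = tt, func = f, parms = NULL,
                      rtol = 1e-10, atol = 1e-12)
  late <- tt >= 38 * q$Tc
  pd <- downstream_pressure(tt[late], wk, q, base)
  expect_lt(max(abs(pd - sol[late, 2])) / max(abs(pd)), 1e-6)
})

test_that("downstream pressure is periodic and nonnegative", {
  wk <- windkessel_params()
  q <- aortic_flow_model()
  tt <- seq(0, q$Tc, length.out = 500)
  pd <- downstream_pressure(tt, wk, q, baseline = 2)
  expect_lt(max(abs(downstream_pressure(tt + q$Tc, wk, q, 2) - pd)),
            1e-8 * max(abs(pd)))
  expect_true(all(pd >= 0))
})
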