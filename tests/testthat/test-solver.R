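# Solver verification on channel benchmarks and short tree runs.

test_that("steady Stokes channel flow reproduces the Poiseuille parabola,
           flux and pressure gradient", {
  px <- poiseuille_setup()
  meta <- px$m$vertex_meta
  u <- px$ini$state$u
  # mid-channel profile vs 1.5 I0 (1 - (y/h)^2), I(0) = 10 cm/s
  midv <- which(abs(meta$s - 1.5) < 1e-9)
  y <- meta$n[midv] * 0.01
  hh <- 0.0015
  exact <- 1.5 * 0.1 * (1 - (y / hh)^2)
  expect_lt(max(abs(u[midv] - exact)) / max(exact), 0.01)
  # flux: mean speed x width = 3 cm^3/s, inflow negative
  expect_equal(boundary_flux(px$sp, u, "inlet"), -3, tolerance = 1e-8)
  expect_equal(boundary_flux(px$sp, u, "outlet_1"), 3, tolerance = 1e-8)
  # pressure gradient G = 2 mu U_max / h^2
  p <- px$ini$state$p
  sel <- meta$n == 0 & meta$s > 0.5 & meta$s < 2.5
  fit <- stats::coef(stats::lm(p[sel] ~ I(meta$s[sel] * 0.01)))
  G <- 2 * 0.0032 * 0.15 / 0.0015^2
  expect_lt(abs(-fit[[2]] - G) / G, 0.01)
})

test_that("the initial state is discretely divergence free", {
  px <- poiseuille_setup()
  expect_lt(vffr:::divergence_residual(px$ini$B, px$ini$state$u), 1e-10)
})

test_that("zero inlet forcing yields a hydrostatic rest state", {
  m <- channel_mesh(0.68, 0.1)
  sp <- fem_spaces(m)
  cfg <- simulation_config(waveform = inlet_waveform(Ip = 0, I0 = 0, Ic = 0))
  ini <- initial_state(sp, cfg)
  expect_lt(max(abs(ini$state$u)), 1e-10)
})

test_that("the Carreau operator with mu0 = mu_inf equals the constant-
           viscosity operator entrywise", {
  m <- channel_mesh(0.68, 0.1)
  sp <- fem_spaces(m)
  set.seed(3)
  u <- rnorm(2L * sp$n2, 0, 0.05)
  args <- list(sp$coords_m, sp$mesh$triangles, sp$tri_edges, sp$ne, u)
  k1 <- do.call(vffr:::.assemble_ns, c(args, list(1L, 0, 0.004, 0.004,
                                                  10.03, 0.344, 1060, 5e-3,
                                                  FALSE, TRUE)))
  k2 <- do.call(vffr:::.assemble_ns, c(args, list(0L, 0.004, 0, 0, 1, 1,
                                                  1060, 5e-3, FALSE, TRUE)))
  expect_lt(max(abs(k1$kx - k2$kx)), 1e-12)
  expect_identical(k1$ki, k2$ki)
})

test_that("a Newtonian-limit Carreau run equals the Newtonian code path", {
  m <- channel_mesh(0.68, 0.1)
  cfg1 <- quick_config(fluid = fluid_params(
    model = "carreau", carreau = carreau_params(mu0 = 0.0032,
                                                mu_inf = 0.0032)))
  cfg2 <- quick_config(fluid = fluid_params(model = "newtonian",
                                            newtonian_mu = 0.0032))
  r1 <- run_simulation(m, cfg1)
  r2 <- run_simulation(m, cfg2)
  expect_equal(r1$Pa, r2$Pa, tolerance = 1e-9)
  expect_equal(r1$Q_out_1, r2$Q_out_1, tolerance = 1e-9)
})

test_that("the Windkessel outlet differs from the free outlet by a
           rank-one coupling block", {
  m <- channel_mesh(0.68, 0.1)
  sp <- fem_spaces(m)
  st <- vffr:::new_flow_state(numeric(2L * sp$n2), numeric(sp$n1), 0)
  os <- list(outlet_state(1, P0 = 0, Pd0 = 0))
  cfg_w <- quick_config(outlets = "windkessel")
  cfg_f <- quick_config(outlets = "free")
  sys_w <- assemble_step(sp, st, cfg_w, os, t_new = cfg_w$dt)
  sys_f <- assemble_step(sp, st, cfg_f, os, t_new = cfg_f$dt)
  D <- Matrix::drop0(sys_w$A - sys_f$A, tol = 1e-300)
  nz <- which(sp$bvec[["outlet_1"]] != 0)
  expect_true(all((D@i + 1L) %in% nz)) # support on outlet dofs only
  Dm <- as.matrix(D[nz, nz])
  expect_equal(qr(Dm)$rank, 1L)
})

test_that("run_simulation records one row per step and labels cycles", {
  m <- channel_mesh(0.68, 0.1)
  res <- run_simulation(m, quick_config(n_cycles = 2L))
  spc <- round(0.8 / 0.016)
  expect_equal(nrow(res), 2L * spc)
  expect_equal(unique(res$cycle), c(1L, 2L))
  expect_equal(res$t[nrow(res)], 1.6)
})

test_that("the cached-pattern stepper matches the general assembly path", {
  m <- channel_mesh(0.68, 0.1)
  sp <- fem_spaces(m)
  cfg <- quick_config()
  ini <- initial_state(sp, cfg)
  kinds <- vffr:::resolve_outlets(sp, cfg)$kinds
  stepper <- vffr:::make_stepper(sp, cfg, kinds)
  st_f <- ini$state; os_f <- ini$outlet_states
  st_s <- ini$state; os_s <- ini$outlet_states
  for (i in 1:3) {
    a <- stepper(st_f$u, os_f, i * cfg$dt)
    st_f <- a$state; os_f <- a$outlet_states
    b <- time_step(sp, st_s, cfg, os_s, i * cfg$dt)
    st_s <- b$state; os_s <- b$outlet_states
  }
  expect_lt(max(abs(st_f$u - st_s$u)), 1e-10)
  expect_lt(max(abs(st_f$p - st_s$p)), 1e-6)
})

test_that("mass is conserved at every step on a healthy tree", {
  m <- memo("healthy_tree_mesh",
            mesh(coronary_tree_domain(lesions = FALSE), 0.12))
  res <- run_simulation(m, quick_config())
  qo <- rowSums(as.data.frame(res)[, paste0("Q_out_", 1:4)])
  expect_lt(max(abs(res$Q_in + qo) / abs(res$Q_in)), 1e-3)
})

test_that("kinetic energy decays without forcing through free outlets", {
  m <- channel_mesh(0.68, 0.1)
  sp <- fem_spaces(m)
  cfg_drive <- quick_config(outlets = "free")
  ini <- initial_state(sp, cfg_drive)
  cfg0 <- quick_config(outlets = "free",
                       waveform = inlet_waveform(Ip = 0, I0 = 0, Ic = 0),
                       pd_baseline = 0,
                       pd_flow = aortic_flow_model(Q0 = 0))
  st <- ini$state; os <- ini$outlet_states
  ke <- kinetic_energy(sp, st$u)
  for (i in 1:6) {
    stp <- time_step(sp, st, cfg0, os, i * cfg0$dt)
    st <- stp$state; os <- stp$outlet_states
    ke_new <- kinetic_energy(sp, st$u)
    expect_lt(ke_new, ke * (1 + 1e-12))
    ke <- ke_new
  }
})

test_that("time discretization self-converges at first order", {
  dom <- channel_domain(degree = 0.68)
  m <- channel_mesh(0.68, 0.1)
  final_u <- function(dt) {
    cfg <- simulation_config(dt = dt, n_cycles = 1L)
    spc <- round(0.8 / dt)
    sp <- fem_spaces(m)
    ini <- initial_state(sp, cfg)
    kinds <- vffr:::resolve_outlets(sp, cfg)$kinds
    stepper <- vffr:::make_stepper(sp, cfg, kinds)
    st <- ini$state; os <- ini$outlet_states
    n <- round(0.16 / dt)
    for (i in seq_len(n)) {
      a <- stepper(st$u, os, i * dt)
      st <- a$state; os <- a$outlet_states
    }
    st$u
  }
  u1 <- final_u(0.016); u2 <- final_u(0.008); u3 <- final_u(0.004)
  e1 <- sqrt(sum((u1 - u2)^2))
  e2 <- sqrt(sum((u2 - u3)^2))
  order <- log2(e1 / e2)
  expect_gt(order, 0.8)
})

test_that("identical configurations give bit-identical traces", {
  m <- channel_mesh(0.68, 0.1)
  r1 <- run_simulation(m, quick_config())
  r2 <- run_simulation(m, quick_config())
  expect_identical(r1$Pa, r2$Pa)
  expect_identical(r1$Q_out_1, r2$Q_out_1)
  expect_identical(attr(r1, "provenance")$config_hash,
                   attr(r2, "provenance")$config_hash)
})

test_that("the traction inlet mode drives inflow", {
  m <- channel_mesh(0.68, 0.1)
  sp <- fem_spaces(m)
  cfg <- quick_config(inlet_mode = "traction")
  ini <- initial_state(sp, cfg)
  stp <- time_step(sp, ini$state, cfg, ini$outlet_states, cfg$dt)
  expect_true(all(is.finite(stp$state$u)))
  expect_lt(boundary_flux(sp, stp$state$u, "inlet"), 0)
})

test_that("unknown flux tags error", {
  m <- channel_mesh(0.68, 0.1)
  sp <- fem_spaces(m)
  expect_error(boundary_flux(sp, numeric(2L * sp$n2), "outlet_9"),
               "unknown boundary tag")
})
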