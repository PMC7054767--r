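# Shared fixtures, memoized so that expensive simulations run once per
# test session.  The study conditions (waveform, rheology, Windkessel
# constants, lesion degrees) are the package defaults; the problem sizes
# used here (element size 0.085-0.13 cm, dt = 8 ms, i.e. 100 steps per
# 0.8 s cycle) are the scaled-down grids of the methods vignette.

.fix <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fix[[key]])) .fix[[key]] <- force(expr)
  .fix[[key]]
}

test_config <- function(n_cycles = 5L, dt = 0.008, ...) {
  simulation_config(dt = dt, n_cycles = n_cycles, ...)
}

# quick config for structural / smoke tests
quick_config <- function(n_cycles = 1L, dt = 0.016, ...) {
  simulation_config(dt = dt, n_cycles = n_cycles, ...)
}

channel_mesh <- function(degree = 0.68, h = 0.1, ...) {
  memo(paste0("chmesh_", degree, "_", h),
       mesh(channel_domain(degree = degree, sensor = TRUE, ...), h))
}

# full five-cycle channel run at a given stenosis degree
channel_run <- function(degree, h = 0.1) {
  memo(paste0("chrun_", degree, "_", h), {
    run_simulation(channel_mesh(degree, h), test_config())
  })
}

channel_ffr_a <- function(degree, h = 0.1) {
  res <- channel_run(degree, h)
  rec <- ffr_from_series(res)[[1L]]
  rec$FFR_a[nrow(rec)]
}

# five-cycle two-lesion tree runs under different outlet conditions
tree_run <- function(outlets = "windkessel", h = 0.1) {
  memo(paste0("treerun_", outlets, "_", h), {
    m <- memo(paste0("treemesh_", h), mesh(coronary_tree_domain(), h))
    run_simulation(m, test_config(outlets = outlets))
  })
}

# mesh-refinement study of the single-lesion (56%) tree
tree_convergence <- function() {
  memo("conv", mesh_convergence(test_config(), hs = c(0.12, 0.1, 0.085),
                                lesion = 2L))
}

# sensor-displacement sweeps on the 68% channel, 7 positions per direction
channel_sweep <- function(direction) {
  memo(paste0("sweep_", direction),
       sensor_sweep(test_config(), direction = direction, n_positions = 7L,
                    h = 0.1))
}

# steady Stokes Poiseuille benchmark (channel, constant viscosity)
poiseuille_setup <- function() {
  memo("poiseuille", {
    dom <- channel_domain(length = 3, diameter = 0.3, degree = 0,
                          sensor = FALSE)
    m <- mesh(dom, 0.05)
    sp <- fem_spaces(m)
    cfg <- simulation_config(fluid = fluid_params(model = "newtonian",
                                                  newtonian_mu = 0.0032),
                             outlets = "free")
    ini <- initial_state(sp, cfg)
    list(m = m, sp = sp, cfg = cfg, ini = ini)
  })
}
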