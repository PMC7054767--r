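# Semi-implicit time integration of the generalized (Carreau) Navier-Stokes
# system with Taylor-Hood elements: backward Euler in time, viscosity
# evaluated at the lagged shear rate, convection linearized about the lagged
# velocity, Windkessel outlets coupled through implicit resistive rank-one
# blocks plus explicit traction loads.
#
# Two assembly paths share the same element kernel: a general one building
# the full sparse system (assemble_step / time_step), and a cached
# fixed-pattern path used by run_simulation, which pre-computes the reduced
# CSC layout once and only refreshes values each step.

#' Simulation configuration
#'
#' Collects the physical and numerical settings of a run. The defaults are
#' the study conditions: `dt = 5e-3` s, five cardiac cycles of `Tc = 0.8` s,
#' Carreau blood rheology, the pulsatile coronary inlet waveform, and
#' identical 2-element Windkessel models on every outlet.
#'
#' @param dt Time step, s; `Tc / dt` must be an integer.
#' @param n_cycles Number of cardiac cycles (`>= 1`).
#' @param fluid A [fluid_params()] object.
#' @param waveform An [inlet_waveform()] object.
#' @param wk A [windkessel_params()] object (shared by all Windkessel
#'   outlets).
#' @param pd_flow An [aortic_flow_model()] driving the downstream pressure.
#' @param pd_baseline Downstream baseline pressure, mmHg.
#' @param outlets `"windkessel"`, `"free"`, `"mixed"` (longest terminal
#'   branch free, others Windkessel), a character vector of per-outlet
#'   kinds, or an [outlet_bc_assignment()].
#' @param inlet_mode `"dirichlet_poiseuille"` (parabolic profile whose
#'   spatial mean equals the waveform speed) or `"traction"` (the waveform
#'   value applied as a normal traction in mmHg).
#' @param probe A [probe_spec()] for the aortic sampling box.
#' @param body_force Constant body force (N/m^3), length 2.
#' @param snapshots Record velocity/pressure fields at peak systole and
#'   peak diastole of the final cycle?
#' @param outlet_P0 Initial outlet pressure, mmHg (`NULL`: the downstream
#'   pressure at `t = 0`).
#' @param seed Integer seed recorded with the run (the solver itself is
#'   deterministic).
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(dt = 5e-3, n_cycles = 5L,
                              fluid = fluid_params(),
                              waveform = inlet_waveform(),
                              wk = windkessel_params(),
                              pd_flow = aortic_flow_model(),
                              pd_baseline = 2,
                              outlets = "windkessel",
                              inlet_mode = c("dirichlet_poiseuille", "traction"),
                              probe = probe_spec(),
                              body_force = c(0, 0),
                              snapshots = FALSE,
                              outlet_P0 = NULL,
                              seed = 1L) {
  inlet_mode <- match.arg(inlet_mode)
  stopifnot(dt > 0, n_cycles >= 1L)
  Tc <- waveform$Tc
  spc <- Tc / dt
  if (abs(spc - round(spc)) > 1e-9) {
    stop("Tc / dt must be an integer number of steps")
  }
  structure(list(dt = dt, n_cycles = as.integer(n_cycles), Tc = Tc,
                 fluid = fluid, waveform = waveform, wk = wk,
                 pd_flow = pd_flow, pd_baseline = pd_baseline,
                 outlets = outlets, inlet_mode = inlet_mode, probe = probe,
                 body_force = body_force, snapshots = snapshots,
                 outlet_P0 = outlet_P0, seed = as.integer(seed)),
            class = "simulation_config")
}

# Resolve the outlet assignment against a concrete mesh.
resolve_outlets <- function(spaces, config) {
  nk <- length(spaces$outlet_tags)
  out <- config$outlets
  if (inherits(out, "outlet_bc_assignment")) {
    kinds <- out$kinds
    wk <- out$params
  } else if (is.character(out) && length(out) == 1L) {
    wk <- config$wk
    kinds <- switch(out,
      windkessel = rep("windkessel", nk),
      free = rep("free", nk),
      mixed = {
        dom <- spaces$mesh$domain
        if (is.null(dom)) {
          stop("mixed outlet BC needs the parametric domain to find the longest branch")
        }
        k <- rep("windkessel", nk)
        k[longest_terminal(dom)$outlet_id] <- "free"
        k
      },
      stop("unknown outlet assignment: ", out))
  } else {
    kinds <- as.character(out)
    wk <- config$wk
  }
  if (length(kinds) != nk) {
    stop("outlet assignment has ", length(kinds), " kinds for ", nk, " outlets")
  }
  list(kinds = kinds, wk = wk)
}

# Downstream pressure at time t under the configured model.
config_pd <- function(config, t) {
  downstream_pressure(t, config$wk, config$pd_flow, config$pd_baseline)
}

# Fixed Dirichlet dof pattern (indices) shared by both assembly paths.
# Wall/sensor no-slip dofs carry zeros; inlet dofs carry the parabolic
# profile scaled by I(t) (Dirichlet inlet mode only).
dirichlet_pattern <- function(spaces, config) {
  n2 <- spaces$n2
  idx <- integer(0)
  prof <- numeric(0)
  dirx <- c(0, 0)
  if (config$inlet_mode == "dirichlet_poiseuille") {
    inl <- spaces$inlet
    if (is.null(inl)) stop("mesh has no inlet boundary")
    idx <- c(inl$dofs, n2 + inl$dofs)
    shape <- 1 - (2 * inl$xi / inl$width)^2
    prof <- c(shape * inl$dir[1], shape * inl$dir[2])
  }
  wall_tags <- intersect(c("wall", spaces$sensor_tags), spaces$tags)
  wdofs <- sort(unique(unlist(spaces$dofs[wall_tags])))
  idx <- c(idx, wdofs, n2 + wdofs)
  prof <- c(prof, numeric(2L * length(wdofs)))
  # walls override the inlet profile at shared corner nodes (both zero)
  dup <- duplicated(idx)
  idx <- idx[!dup]; prof <- prof[!dup]
  if (length(spaces$outlet_tags) == 0L) {
    idx <- c(idx, 2L * n2 + 1L) # pin the pressure gauge
    prof <- c(prof, 0)
  }
  list(idx = idx, prof = prof)
}

# Dirichlet values at time t: the profile scaled by the inlet mean speed.
dirichlet_values <- function(pat, config, t) {
  if (config$inlet_mode == "dirichlet_poiseuille") {
    umax <- 1.5 * inlet_speed(t, config$waveform) * M_PER_CM
    pat$prof * umax
  } else {
    pat$prof
  }
}

body_force_rhs <- function(spaces, config, rhs) {
  if (all(config$body_force == 0)) return(rhs)
  tr <- spaces$mesh$triangles
  v <- spaces$coords_m
  a2 <- (v[tr[, 2], 1] - v[tr[, 1], 1]) * (v[tr[, 3], 2] - v[tr[, 1], 2]) -
    (v[tr[, 2], 2] - v[tr[, 1], 2]) * (v[tr[, 3], 1] - v[tr[, 1], 1])
  area <- abs(a2) / 2
  f <- config$body_force
  for (le in 1:3) { # only the edge bubbles carry P2 unit-integral mass
    md <- spaces$nv + spaces$tri_edges[, le]
    rhs[md] <- rhs[md] + f[1] * area / 3
    rhs[spaces$n2 + md] <- rhs[spaces$n2 + md] + f[2] * area / 3
  }
  rhs
}

# mmHg-per-(cm^3/s) resistance to SI traction per (m^2/s) flux
R_SI <- function(R_mmhg) R_mmhg * PA_PER_MMHG * 1e4

# Kernel call + global sparse system for one step (general path).
assemble_system <- function(spaces, u_lag, config, outlet_states, kinds,
                            t_new, steady = FALSE, constant_mu = NULL) {
  if (any(!is.finite(u_lag))) {
    stop("non-finite lagged velocity at t = ", t_new,
         "; the previous step diverged")
  }
  n2 <- spaces$n2; n1 <- spaces$n1
  fl <- config$fluid
  if (!is.null(constant_mu)) {
    vm <- 0L; mu_c <- constant_mu
  } else if (fl$model == "newtonian") {
    vm <- 0L; mu_c <- fl$newtonian_mu
  } else {
    vm <- 1L; mu_c <- 0
  }
  cp <- fl$carreau
  k <- .assemble_ns(spaces$coords_m, spaces$mesh$triangles, spaces$tri_edges,
                    spaces$ne, u_lag, vm, mu_c, cp$mu0, cp$mu_inf,
                    cp$lambda, cp$n, fl$rho, config$dt,
                    steady, !steady)
  ndof <- 2L * n2 + n1
  ti <- c(k$ki, k$bj, 2L * n2 + k$bi)
  tj <- c(k$kj, 2L * n2 + k$bi, k$bj)
  tx <- c(k$kx, -k$bx, k$bx)
  rhs <- body_force_rhs(spaces, config, c(k$rhs, numeric(n1)))

  Pd_n <- config_pd(config, t_new)
  splits <- vector("list", length(spaces$outlet_tags))
  for (kk in seq_along(spaces$outlet_tags)) {
    tg <- spaces$outlet_tags[kk]
    sp <- outlet_traction_split(outlet_states[[kk]], config$wk, Pd_n,
                                config$dt, kinds[kk])
    splits[[kk]] <- sp
    if (kinds[kk] == "free") next
    b <- spaces$bvec[[tg]]
    nzi <- which(b != 0)
    bv <- b[nzi]
    ti <- c(ti, rep(nzi, each = length(nzi)))
    tj <- c(tj, rep(nzi, times = length(nzi)))
    tx <- c(tx, R_SI(sp$implicit_R) * as.numeric(outer(bv, bv)))
    rhs[nzi] <- rhs[nzi] - mmhg_to_pa(sp$explicit_traction) * bv
  }

  I_t <- inlet_speed(t_new, config$waveform) # cm/s
  if (config$inlet_mode == "traction") {
    rhs <- rhs - mmhg_to_pa(I_t) * c(spaces$bvec[["inlet"]], numeric(n1))
  }
  pat <- dirichlet_pattern(spaces, config)
  dir_idx <- pat$idx
  dir_val <- dirichlet_values(pat, config, t_new)

  A <- Matrix::sparseMatrix(i = ti, j = tj, x = tx, dims = c(ndof, ndof))
  B <- Matrix::sparseMatrix(i = k$bi, j = k$bj, x = k$bx,
                            dims = c(n1, 2L * n2))
  list(A = A, B = B, rhs = rhs, dir_idx = dir_idx, dir_val = dir_val,
       splits = splits, Pd_n = Pd_n, I_t = I_t)
}

#' Assemble the linear system of one implicit step
#'
#' Backward-Euler/semi-implicit assembly about the lagged state: viscous
#' form with the Carreau viscosity frozen at the previous shear-rate field,
#' convection linearized as `b(u_n, u_{n+1}, v)`, incompressibility
#' constraint, Windkessel outlets as implicit rank-one resistive couplings
#' plus explicit traction loads, inlet and no-slip conditions per the
#' configuration.
#'
#' @param spaces A [fem_spaces()] object.
#' @param state A `flow_state` (the lagged state).
#' @param config A [simulation_config()].
#' @param outlet_states List of [outlet_state()] objects, one per outlet.
#' @param t_new Time being stepped to, s.
#' @return List with the sparse system matrix `A`, divergence operator
#'   `B`, right-hand side, Dirichlet index/value vectors, and per-outlet
#'   traction splits.
#' @export
assemble_step <- function(spaces, state, config, outlet_states, t_new) {
  kinds <- resolve_outlets(spaces, config)$kinds
  assemble_system(spaces, state$u, config, outlet_states, kinds, t_new)
}

solve_sparse <- function(A, rhs, dir_idx, dir_val) {
  ndof <- length(rhs)
  x <- numeric(ndof)
  if (length(dir_idx)) {
    x[dir_idx] <- dir_val
    free <- setdiff(seq_len(ndof), dir_idx)
    rhs_f <- rhs[free] - as.numeric(A[free, dir_idx, drop = FALSE] %*% dir_val)
  } else {
    free <- seq_len(ndof)
    rhs_f <- rhs
  }
  sol <- tryCatch({
    # fill-reducing ordering 3 (AMD of the squared pattern) factors this
    # saddle-point structure markedly faster than the default
    fac <- Matrix::lu(A[free, free, drop = FALSE], order = 3L)
    Matrix::solve(fac, rhs_f)
  },
    error = function(e) {
      stop("linear solve failed: ", conditionMessage(e),
           " (singular system; check boundary conditions / pressure gauge)")
    })
  x[free] <- as.numeric(sol)
  x
}

new_flow_state <- function(u, p_pa, t) {
  structure(list(u = u, p = p_pa, t = t), class = "flow_state")
}

#' @export
print.flow_state <- function(x, ...) {
  cat("<flow_state> t = ", x$t, " s, max |u| = ",
      signif(max(abs(x$u)), 4), " m/s\n", sep = "")
  invisible(x)
}

#' Steady Stokes initial state
#'
#' Solves the steady Stokes problem with constant viscosity (the zero-shear
#' Carreau value, or the Newtonian constant) and the inlet profile at
#' `I(0)`, with the configured outlet conditions at their initial instant.
#' The returned velocity is discretely divergence free.
#'
#' @param spaces A [fem_spaces()] object.
#' @param config A [simulation_config()].
#' @return List with `state` (a `flow_state`), `outlet_states` (advanced to
#'   the initial fluxes), `kinds`, and the divergence operator `B`.
#' @export
initial_state <- function(spaces, config) {
  kinds <- resolve_outlets(spaces, config)$kinds
  mu0 <- if (config$fluid$model == "newtonian") {
    config$fluid$newtonian_mu
  } else {
    config$fluid$carreau$mu0
  }
  Pd0 <- config_pd(config, 0)
  P0 <- if (is.null(config$outlet_P0)) Pd0 else config$outlet_P0
  outlet_states <- lapply(seq_along(spaces$outlet_tags), function(k) {
    outlet_state(k, P0 = P0, Q_init = 0, Pd0 = Pd0)
  })
  sys <- assemble_system(spaces, numeric(2L * spaces$n2), config,
                         outlet_states, kinds, t_new = 0, steady = TRUE,
                         constant_mu = mu0)
  x <- solve_sparse(sys$A, sys$rhs, sys$dir_idx, sys$dir_val)
  u <- x[seq_len(2L * spaces$n2)]
  p <- x[2L * spaces$n2 + seq_len(spaces$n1)]
  for (k in seq_along(outlet_states)) {
    if (kinds[k] == "free") next
    Q <- boundary_flux(spaces, u, spaces$outlet_tags[k])
    P_mm <- sys$splits[[k]]$implicit_R * Q + sys$splits[[k]]$explicit_traction
    outlet_states[[k]] <- outlet_state_advance(outlet_states[[k]], config$wk,
                                               Q, P_mm, sys$Pd_n, config$dt)
  }
  list(state = new_flow_state(u, p, 0), outlet_states = outlet_states,
       kinds = kinds, B = sys$B)
}

#' Advance one time step
#'
#' Solves the assembled sparse system, advances the outlet histories with
#' the new fluxes, and returns the new state.
#'
#' @param spaces A [fem_spaces()] object.
#' @param state The lagged `flow_state`.
#' @param config A [simulation_config()].
#' @param outlet_states Per-outlet [outlet_state()] list.
#' @param t_new New time, s.
#' @return List with `state`, `outlet_states`, per-outlet fluxes `Q`
#'   (cm^3/s) and pressures `P` (mmHg).
#' @export
time_step <- function(spaces, state, config, outlet_states, t_new) {
  kinds <- resolve_outlets(spaces, config)$kinds
  sys <- assemble_system(spaces, state$u, config, outlet_states, kinds, t_new)
  x <- solve_sparse(sys$A, sys$rhs, sys$dir_idx, sys$dir_val)
  u <- x[seq_len(2L * spaces$n2)]
  p <- x[2L * spaces$n2 + seq_len(spaces$n1)]
  Qs <- Ps <- rep(NA_real_, length(outlet_states))
  for (k in seq_along(outlet_states)) {
    Q <- boundary_flux(spaces, u, spaces$outlet_tags[k])
    Qs[k] <- Q
    if (kinds[k] == "free") next
    P_mm <- sys$splits[[k]]$implicit_R * Q + sys$splits[[k]]$explicit_traction
    Ps[k] <- P_mm
    outlet_states[[k]] <- outlet_state_advance(outlet_states[[k]], config$wk,
                                               Q, P_mm, sys$Pd_n, config$dt)
  }
  list(state = new_flow_state(u, p, t_new), outlet_states = outlet_states,
       Q = Qs, P = Ps, B = sys$B)
}

# Cached fixed-pattern stepper.  Builds the reduced CSC layout once (the
# sparsity pattern is constant along the time loop) and refreshes only the
# numeric values each step.
make_stepper <- function(spaces, config, kinds) {
  n2 <- spaces$n2; n1 <- spaces$n1
  ndof <- 2L * n2 + n1
  fl <- config$fluid
  cp <- fl$carreau
  vm <- if (fl$model == "newtonian") 0L else 1L
  mu_c <- if (vm == 0L) fl$newtonian_mu else 0

  pat <- dirichlet_pattern(spaces, config)
  redmap <- integer(ndof)
  freeidx <- setdiff(seq_len(ndof), pat$idx)
  redmap[freeidx] <- seq_along(freeidx)
  nfree <- length(freeidx)

  # pattern from one triplet-kernel call (values discarded)
  k0 <- .assemble_ns(spaces$coords_m, spaces$mesh$triangles, spaces$tri_edges,
                     spaces$ne, numeric(2L * n2), 0L, 1, 1, 1, 1, 1,
                     1, 1, FALSE, TRUE)
  rK <- redmap[k0$ki]; cK <- redmap[k0$kj]
  rB <- redmap[2L * n2 + k0$bi]; cB <- redmap[k0$bj]
  rT <- redmap[k0$bj]; cT <- redmap[2L * n2 + k0$bi]
  keepK <- rK > 0L & cK > 0L
  keepB <- rB > 0L & cB > 0L
  keepT <- rT > 0L & cT > 0L

  wk_idx <- which(kinds == "windkessel")
  ro <- lapply(wk_idx, function(kk) {
    b <- spaces$bvec[[spaces$outlet_tags[kk]]]
    nzi <- which(b != 0 & redmap[seq_len(2L * n2)] > 0L)
    list(outlet = kk, nzi = nzi, bv = b[nzi],
         red = redmap[nzi],
         ov = as.numeric(outer(b[nzi], b[nzi])))
  })

  pi_ <- c(rK[keepK], rB[keepB], rT[keepT],
           unlist(lapply(ro, function(o) rep(o$red, each = length(o$red)))))
  pj_ <- c(cK[keepK], cB[keepB], cT[keepT],
           unlist(lapply(ro, function(o) rep(o$red, times = length(o$red)))))
  Af0 <- Matrix::sparseMatrix(i = pi_, j = pj_, x = rep(1, length(pi_)),
                              dims = c(nfree, nfree))
  csckey <- (rep(seq_len(nfree), diff(Af0@p)) - 1) * nfree +
    as.numeric(Af0@i + 1L)
  slot_of <- function(r, c_) match((c_ - 1) * nfree + r, csckey)
  slotK <- integer(length(rK)); slotK[keepK] <- slot_of(rK[keepK], cK[keepK])
  slotB <- integer(length(rB)); slotB[keepB] <- slot_of(rB[keepB], cB[keepB])
  slotTB <- integer(length(rT)); slotTB[keepT] <- slot_of(rT[keepT], cT[keepT])
  for (oi in seq_along(ro)) {
    ro[[oi]]$slots <- slot_of(rep(ro[[oi]]$red, each = length(ro[[oi]]$red)),
                              rep(ro[[oi]]$red, times = length(ro[[oi]]$red)))
  }
  nnz <- length(Af0@x)

  b_inlet_red <- NULL
  if (config$inlet_mode == "traction") {
    bi_ <- spaces$bvec[["inlet"]]
    b_inlet_red <- numeric(nfree)
    nz <- which(bi_ != 0 & redmap[seq_len(2L * n2)] > 0L)
    b_inlet_red[redmap[nz]] <- bi_[nz]
  }

  function(u_lag, outlet_states, t_new) {
    if (any(!is.finite(u_lag))) {
      stop("non-finite lagged velocity at t = ", t_new,
           "; the previous step diverged")
    }
    dirval <- numeric(ndof)
    dirval[pat$idx] <- dirichlet_values(pat, config, t_new)
    fill <- .assemble_fill(spaces$coords_m, spaces$mesh$triangles,
                           spaces$tri_edges, spaces$ne, u_lag,
                           vm, mu_c, cp$mu0, cp$mu_inf, cp$lambda, cp$n,
                           fl$rho, config$dt, FALSE, TRUE,
                           slotK, slotB, slotTB, redmap, dirval, nnz, nfree)
    xs <- fill$xs
    rhs_full <- body_force_rhs(spaces, config, c(fill$rhs, numeric(n1)))
    Pd_n <- config_pd(config, t_new)
    splits <- vector("list", length(kinds))
    for (o in ro) {
      sp <- outlet_traction_split(outlet_states[[o$outlet]], config$wk, Pd_n,
                                  config$dt, "windkessel")
      splits[[o$outlet]] <- sp
      xs[o$slots] <- xs[o$slots] + R_SI(sp$implicit_R) * o$ov
      rhs_full[o$nzi] <- rhs_full[o$nzi] -
        mmhg_to_pa(sp$explicit_traction) * o$bv
    }
    rhs_red <- rhs_full[freeidx] - fill$rhsdir
    if (!is.null(b_inlet_red)) {
      rhs_red <- rhs_red -
        mmhg_to_pa(inlet_speed(t_new, config$waveform)) * b_inlet_red
    }
    Af <- Af0
    Af@x <- xs
    sol <- tryCatch(
      Matrix::solve(Matrix::lu(Af, order = 3L), rhs_red),
      error = function(e) {
        stop("linear solve failed at t = ", t_new, ": ",
             conditionMessage(e))
      })
    x <- numeric(ndof)
    x[freeidx] <- as.numeric(sol)
    x[pat$idx] <- dirval[pat$idx]
    u <- x[seq_len(2L * n2)]
    p <- x[2L * n2 + seq_len(n1)]
    Qs <- Ps <- rep(NA_real_, length(kinds))
    for (kk in seq_along(kinds)) {
      Q <- boundary_flux(spaces, u, spaces$outlet_tags[kk])
      Qs[kk] <- Q
      if (kinds[kk] == "free") next
      sp <- splits[[kk]]
      P_mm <- sp$implicit_R * Q + sp$explicit_traction
      Ps[kk] <- P_mm
      outlet_states[[kk]] <- outlet_state_advance(outlet_states[[kk]],
                                                  config$wk, Q, P_mm, Pd_n,
                                                  config$dt)
    }
    list(state = new_flow_state(u, p, t_new), outlet_states = outlet_states,
         Q = Qs, P = Ps)
  }
}

#' Run a pulsatile simulation
#'
#' Integrates `n_cycles` cardiac cycles from the steady Stokes initial
#' state, recording per-step probe pressures (aortic box and each sensor
#' contour), inlet and outlet fluxes, and optionally field snapshots at
#' peak systole (`Tsys / 2`) and peak diastole (midpoint of the diastolic
#' phase) of the final cycle.
#'
#' @param m A `mesh_domain`.
#' @param config A [simulation_config()].
#' @param init Optional `list(state, outlet_states)` to continue from
#'   (defaults to [initial_state()]).
#' @return A `result_series`: a tibble with one row per time step and
#'   columns `step`, `t`, `cycle`, `Pa` (mmHg), `Pdistal_<m>` (mmHg),
#'   `Q_in`, `Q_out_<k>` (cm^3/s), `inlet_speed` (cm/s); attributes carry
#'   the configuration, outlet kinds, mesh statistics, snapshots, the
#'   final state and a provenance block.
#' @export
run_simulation <- function(m, config = simulation_config(), init = NULL) {
  spaces <- fem_spaces(m)
  spc <- as.integer(round(config$Tc / config$dt))
  n_steps <- spc * config$n_cycles
  if (is.null(init)) init <- initial_state(spaces, config)
  state <- init$state
  outlet_states <- init$outlet_states
  kinds <- resolve_outlets(spaces, config)$kinds
  stepper <- make_stepper(spaces, config, kinds)

  box_idx <- aortic_box_vertices(m, config$probe)
  sens_idx <- lapply(spaces$sensor_tags, function(tg) {
    sort(unique(as.integer(unlist(
      m$boundary[m$boundary$tag == tg, c("v1", "v2")]))))
  })
  n_out <- length(spaces$outlet_tags)
  n_sens <- length(spaces$sensor_tags)

  Pa <- numeric(n_steps)
  Pdist <- matrix(NA_real_, n_steps, n_sens)
  Qout <- matrix(NA_real_, n_steps, n_out)
  Qin <- numeric(n_steps)
  Ispd <- numeric(n_steps)

  # snapshot instants in the final cycle
  wf <- config$waveform
  t_peaks <- (config$n_cycles - 1L) * config$Tc +
    c(systole = wf$Tsys / 2, diastole = wf$Tsys + (config$Tc - wf$Tsys) / 2)
  snap_steps <- as.integer(round(t_peaks / config$dt))
  snaps <- list()

  for (sn in seq_len(n_steps)) {
    t_new <- sn * config$dt
    stp <- stepper(state$u, outlet_states, t_new)
    state <- stp$state
    outlet_states <- stp$outlet_states
    p_mm <- pa_to_mmhg(state$p)
    Pa[sn] <- mean(p_mm[box_idx])
    for (ms in seq_len(n_sens)) Pdist[sn, ms] <- mean(p_mm[sens_idx[[ms]]])
    Qout[sn, ] <- stp$Q
    Qin[sn] <- boundary_flux(spaces, state$u, "inlet")
    Ispd[sn] <- inlet_speed(t_new, wf)
    if (config$snapshots && sn %in% snap_steps) {
      lbl <- names(t_peaks)[match(sn, snap_steps)]
      snaps[[lbl]] <- list(
        t = t_new,
        velocity = cbind(state$u[seq_len(spaces$nv)],
                         state$u[spaces$n2 + seq_len(spaces$nv)]) / M_PER_CM,
        pressure = p_mm)
    }
  }

  res <- tibble::tibble(
    step = seq_len(n_steps),
    t = seq_len(n_steps) * config$dt,
    cycle = ((seq_len(n_steps) - 1L) %/% spc) + 1L,
    Pa = Pa)
  for (ms in seq_len(n_sens)) res[[paste0("Pdistal_", ms)]] <- Pdist[, ms]
  res$Q_in <- Qin
  for (k in seq_len(n_out)) res[[paste0("Q_out_", k)]] <- Qout[, k]
  res$inlet_speed <- Ispd

  structure(res,
            class = c("result_series", class(res)),
            config = config, kinds = kinds,
            mesh_stats = list(nv = nrow(m$vertices),
                              nt = nrow(m$triangles), h = m$h),
            snapshots = snaps,
            final_state = state,
            provenance = list(
              config_hash = rlang::hash(config),
              mesh_hash = rlang::hash(list(m$vertices, m$triangles)),
              dofs = 2L * spaces$n2 + spaces$n1))
}

#' Kinetic energy of a velocity field
#'
#' `0.5 rho int |u|^2 dx` (per unit depth), J/m.
#'
#' @param spaces A [fem_spaces()] object.
#' @param u Velocity dof vector (SI) or `flow_state`.
#' @param rho Density, kg/m^3.
#' @return Scalar energy.
#' @export
kinetic_energy <- function(spaces, u, rho = 1060) {
  if (inherits(u, "flow_state")) u <- u$u
  k <- .assemble_ns(spaces$coords_m, spaces$mesh$triangles, spaces$tri_edges,
                    spaces$ne, numeric(2L * spaces$n2), 0L, 0, 0, 0, 1, 1,
                    rho, 1, FALSE, FALSE)
  M <- Matrix::sparseMatrix(i = k$ki, j = k$kj, x = k$kx,
                            dims = c(2L * spaces$n2, 2L * spaces$n2))
  0.5 * as.numeric(u %*% (M %*% u))
}
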