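# Config-driven experiment drivers: mesh-refinement convergence of the FFR
# estimate, the outlet-BC x flow-model grid, sensor-displacement sweeps,
# and peak-phase field comparisons.  Every driver returns a tibble with a
# provenance attribute (config and mesh hashes, solver settings) so that
# identical inputs are recognizably identical outputs.

exp_provenance <- function(config, extra = list()) {
  c(list(config_hash = rlang::hash(config),
         dt = config$dt, n_cycles = config$n_cycles,
         package_version = as.character(utils::packageVersion("vffr"))),
    extra)
}

run_ffr_a <- function(domain, h, config) {
  m <- mesh(domain, h)
  res <- run_simulation(m, config)
  recs <- ffr_from_series(res)
  list(mesh = m, res = res, recs = recs)
}

#' Mesh-refinement convergence of the FFR estimate
#'
#' Re-meshes the single-lesion study tree at a sequence of element sizes
#' and reports the per-cycle FFR and running average for each grid,
#' together with the stabilization diagnostics: the change of the running
#' average from cycle 3 to the final cycle on each grid, and its change
#' between the two finest grids. A meshing or solver failure at one size
#' yields a flagged row rather than aborting the study.
#'
#' @param config A [simulation_config()].
#' @param hs Decreasing element sizes, cm (at least 2).
#' @param domain The domain to study; default: the synthetic coronary tree
#'   carrying only the selected lesion.
#' @param lesion Which packaged lesion the single-lesion default tree
#'   carries (1 = 68%, 2 = 56%).
#' @return An `ffr_convergence` tibble: one row per mesh with `h`, `nv`,
#'   `nt`, `FFR_c1..c<n>`, `FFRa_c1..c<n>`, `stab_cycle`
#'   (`|FFR_a(final) - FFR_a(3)|`) and `ok`.
#' @export
mesh_convergence <- function(config = simulation_config(),
                             hs = c(0.12, 0.1, 0.085),
                             domain = NULL, lesion = 2L) {
  stopifnot(length(hs) >= 1L)
  if (is.null(domain)) domain <- coronary_tree_domain(lesions = lesion)
  hs <- sort(hs, decreasing = TRUE)
  nc <- config$n_cycles
  rows <- lapply(hs, function(h) {
    out <- tryCatch({
      r <- run_ffr_a(domain, h, config)
      rec <- r$recs[[1L]]
      row <- tibble::tibble(h = h, nv = nrow(r$mesh$vertices),
                            nt = nrow(r$mesh$triangles), ok = TRUE)
      for (k in seq_len(nc)) row[[paste0("FFR_c", k)]] <- rec$FFR[k]
      for (k in seq_len(nc)) row[[paste0("FFRa_c", k)]] <- rec$FFR_a[k]
      row$stab_cycle <- if (nc >= 3L) abs(rec$FFR_a[nc] - rec$FFR_a[3L]) else NA_real_
      row
    }, error = function(e) {
      warning("mesh size h = ", h, " failed: ", conditionMessage(e))
      tibble::tibble(h = h, nv = NA_integer_, nt = NA_integer_, ok = FALSE)
    })
    out
  })
  tab <- dplyr::bind_rows(rows)
  okfine <- which(tab$ok)
  stab_mesh <- if (length(okfine) >= 2L) {
    i2 <- utils::tail(okfine, 2L)
    abs(tab[[paste0("FFRa_c", nc)]][i2[2L]] -
          tab[[paste0("FFRa_c", nc)]][i2[1L]])
  } else NA_real_
  structure(tab, class = c("ffr_convergence", class(tab)),
            stab_mesh = stab_mesh,
            provenance = exp_provenance(config, list(hs = hs, lesion = lesion)))
}

#' Outlet-BC x flow-model FFR grid
#'
#' Runs every combination of flow model (Newtonian constant viscosity vs
#' Carreau) and outlet condition (all-Windkessel, all-free, mixed with the
#' longest branch free) on the two-lesion tree and reports the final
#' running-average FFR of each lesion's sensor.
#'
#' @param config A [simulation_config()].
#' @param h Element size, cm.
#' @param domain Domain with at least one sensor; default: the two-lesion
#'   synthetic coronary tree.
#' @param models Subset of `c("newtonian", "carreau")`.
#' @param bcs Subset of `c("windkessel", "free", "mixed")`.
#' @return An `ffr_bc_grid` tibble with columns `model`, `bc`, `lesion`,
#'   `FFR_a`, `class`.
#' @export
bc_model_grid <- function(config = simulation_config(), h = 0.1,
                          domain = NULL,
                          models = c("newtonian", "carreau"),
                          bcs = c("windkessel", "free", "mixed")) {
  if (is.null(domain)) domain <- coronary_tree_domain()
  m <- mesh(domain, h)
  rows <- list()
  for (mdl in models) {
    for (bc in bcs) {
      cfg <- config
      cfg$fluid$model <- mdl
      cfg$outlets <- bc
      res <- run_simulation(m, cfg)
      recs <- ffr_from_series(res)
      for (ls in seq_along(recs)) {
        rec <- recs[[ls]]
        rows[[length(rows) + 1L]] <- tibble::tibble(
          model = mdl, bc = bc, lesion = ls,
          FFR_a = rec$FFR_a[nrow(rec)],
          class = rec$class[nrow(rec)])
      }
    }
  }
  tab <- dplyr::bind_rows(rows)
  structure(tab, class = c("ffr_bc_grid", class(tab)),
            provenance = exp_provenance(config, list(h = h, models = models,
                                                     bcs = bcs)))
}

#' Sensor-displacement sweep
#'
#' Repeats the full simulation with the sensor disk displaced along the
#' flow direction (tangential) or across it (normal), re-meshing the
#' geometry for every position with identical meshing parameters, and
#' reports the final running-average FFR and its single-cutoff (0.75)
#' classification at each admissible position, plus the number of
#' classification flips along the sweep.
#'
#' @param config A [simulation_config()].
#' @param direction `"normal"` or `"tangential"`.
#' @param offsets Displacements in units of the reference diameter;
#'   default: `n_positions` values spanning -3/10..3/10 (normal) or
#'   -6/10..6/10 (tangential).
#' @param n_positions Number of sweep positions when `offsets` is `NULL`.
#' @param h Element size, cm.
#' @param domain_fn Function `(normal_offset_cm, tangential_offset_cm)`
#'   returning the domain with the displaced sensor; default: the 68%
#'   single-channel fixture.
#' @param D_ref Reference diameter used to scale the offsets, cm.
#' @param cutoff Classification cutoff for the flip count.
#' @return An `ffr_sweep` tibble with `offset_Dref`, `offset_cm`, `FFR_a`,
#'   `class`, `ok`; attribute `n_flips` counts classification changes
#'   between consecutive admissible positions.
#' @export
sensor_sweep <- function(config = simulation_config(),
                         direction = c("normal", "tangential"),
                         offsets = NULL, n_positions = 26L, h = 0.1,
                         domain_fn = NULL, D_ref = 0.3, cutoff = 0.75) {
  direction <- match.arg(direction)
  if (is.null(offsets)) {
    lim <- if (direction == "normal") 3 / 10 else 6 / 10
    offsets <- seq(-lim, lim, length.out = n_positions)
  }
  if (is.null(domain_fn)) {
    domain_fn <- function(n_off, t_off) {
      channel_domain(degree = 0.68, normal_offset = n_off,
                     tangential_offset = t_off)
    }
  }
  rows <- lapply(offsets, function(off) {
    n_off <- if (direction == "normal") off * D_ref else 0
    t_off <- if (direction == "tangential") off * D_ref else 0
    tryCatch({
      dom <- domain_fn(n_off, t_off)
      r <- run_ffr_a(dom, h, config)
      rec <- r$recs[[1L]]
      ffra <- rec$FFR_a[nrow(rec)]
      tibble::tibble(offset_Dref = off, offset_cm = n_off + t_off,
                     FFR_a = ffra,
                     class = classify_ffr(ffra, cutoffs = cutoff),
                     ok = TRUE)
    }, error = function(e) {
      warning("offset ", signif(off, 3), " x D_ref skipped: ",
              conditionMessage(e))
      tibble::tibble(offset_Dref = off, offset_cm = NA_real_,
                     FFR_a = NA_real_,
                     class = factor(NA, levels = levels(classify_ffr(1))),
                     ok = FALSE)
    })
  })
  tab <- dplyr::bind_rows(rows)
  cls <- as.integer(tab$class[tab$ok])
  n_flips <- if (length(cls) > 1L) sum(diff(cls) != 0L) else 0L
  structure(tab, class = c("ffr_sweep", class(tab)),
            direction = direction, n_flips = n_flips, cutoff = cutoff,
            provenance = exp_provenance(config, list(h = h,
                                                     direction = direction)))
}

#' Peak-phase field comparison
#'
#' Runs the requested flow-model x outlet-BC combinations with field
#' snapshots enabled and writes velocity/pressure VTU files at peak
#' systole and peak diastole of the final cycle.
#'
#' @param config A [simulation_config()].
#' @param h Element size, cm.
#' @param domain Domain to simulate; default: the two-lesion tree.
#' @param models,bcs Combinations to run.
#' @param out_dir Directory for the VTU files (created if needed).
#' @return A tibble manifest (`model`, `bc`, `phase`, `t`, `path`) with
#'   the snapshot fields attached as an attribute.
#' @export
field_comparison <- function(config = simulation_config(), h = 0.1,
                             domain = NULL,
                             models = "carreau", bcs = c("windkessel", "free"),
                             out_dir = tempdir()) {
  if (is.null(domain)) domain <- coronary_tree_domain()
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  m <- mesh(domain, h)
  rows <- list()
  fields <- list()
  for (mdl in models) {
    for (bc in bcs) {
      cfg <- config
      cfg$fluid$model <- mdl
      cfg$outlets <- bc
      cfg$snapshots <- TRUE
      res <- run_simulation(m, cfg)
      snaps <- attr(res, "snapshots")
      for (ph in names(snaps)) {
        path <- file.path(out_dir, sprintf("fields_%s_%s_%s.vtu",
                                           mdl, bc, ph))
        write_vtu(m, path, point_data = list(
          velocity = snaps[[ph]]$velocity,
          pressure = snaps[[ph]]$pressure))
        rows[[length(rows) + 1L]] <- tibble::tibble(
          model = mdl, bc = bc, phase = ph, t = snaps[[ph]]$t, path = path)
        fields[[paste(mdl, bc, ph, sep = "_")]] <- snaps[[ph]]
      }
    }
  }
  tab <- dplyr::bind_rows(rows)
  structure(tab, class = c("field_set", class(tab)), fields = fields,
            provenance = exp_provenance(config, list(h = h)))
}
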