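# Experiment drivers: structure, provenance and the cheap qualitative
# checks (short runs at coarse grids; the five-cycle studies live in
# test-acceptance.R).

test_that("a single-size convergence study yields a one-row table", {
  tab <- mesh_convergence(quick_config(), hs = 0.12,
                          domain = channel_domain(degree = 0.68))
  expect_equal(nrow(tab), 1L)
  expect_true(tab$ok)
  expect_true(all(c("FFR_c1", "FFRa_c1") %in% names(tab)))
  expect_false(is.null(attr(tab, "provenance")$config_hash))
})

test_that("a failing mesh size is flagged, not fatal", {
  expect_warning(
    tab <- mesh_convergence(quick_config(), hs = c(0.9, 0.12),
                            domain = channel_domain(degree = 0.68)),
    "failed")
  expect_equal(tab$ok, c(FALSE, TRUE))
})

test_that("a one-model one-BC grid on the two-lesion tree has one row per
           lesion", {
  tab <- memo("grid_struct",
              bc_model_grid(quick_config(), h = 0.13,
                            models = "carreau", bcs = "windkessel"))
  expect_equal(nrow(tab), 2L)
  expect_equal(tab$lesion, c(1L, 2L))
  expect_true(all(tab$FFR_a > 0))
})

test_that("sensor sweeps skip inadmissible offsets with a warning", {
  expect_warning(
    tab <- sensor_sweep(quick_config(), direction = "normal",
                        offsets = c(0, 0.9), h = 0.12),
    "skipped")
  expect_equal(tab$ok, c(TRUE, FALSE))
  expect_s3_class(tab, "ffr_sweep")
})

test_that("the zero-offset sweep position reproduces the default run", {
  tab <- sensor_sweep(quick_config(), direction = "normal", offsets = 0,
                      h = 0.1)
  m <- channel_mesh(0.68, 0.1)
  res <- run_simulation(m, quick_config())
  rec <- ffr_from_series(res)[[1L]]
  expect_lt(abs(tab$FFR_a[1] - rec$FFR_a[nrow(rec)]), 1e-2)
})

test_that("field comparison writes one snapshot per phase and run, and
           Windkessel vs free pressure fields differ", {
  out <- withr::local_tempdir()
  tab <- memo("fields", {
    field_comparison(quick_config(), h = 0.12,
                     domain = channel_domain(degree = 0.68),
                     models = "carreau", bcs = c("windkessel", "free"),
                     out_dir = out)
  })
  expect_equal(nrow(tab), 2L * 2L) # 2 phases x 2 runs
  expect_true(all(file.exists(tab$path)))
  f <- attr(tab, "fields")
  pw <- f[["carreau_windkessel_diastole"]]$pressure
  pf <- f[["carreau_free_diastole"]]$pressure
  expect_gt(sqrt(sum((pw - pf)^2)) / sqrt(sum(pw^2)), 0.01)
})

test_that("under mixed BCs the free branch runs at lower pressure and
           higher speed than under all-Windkessel BCs", {
  m <- memo("treemesh_0.12", mesh(coronary_tree_domain(), 0.12))
  res_w <- memo("mix_w", run_simulation(m, quick_config(outlets = "windkessel",
                                                        snapshots = TRUE)))
  res_m <- memo("mix_m", run_simulation(m, quick_config(outlets = "mixed",
                                                        snapshots = TRUE)))
  # branch 4 (longest, outlet 1) is the free one under "mixed"
  free_branch <- longest_terminal(coronary_tree_domain())$branch_id
  sel <- m$vertex_meta$branch == free_branch & m$vertex_meta$s > 1
  sw <- attr(res_w, "snapshots")$diastole
  sm <- attr(res_m, "snapshots")$diastole
  expect_lt(mean(sm$pressure[sel]), mean(sw$pressure[sel]))
  spd_w <- sqrt(rowSums(sw$velocity[sel, ]^2))
  spd_m <- sqrt(rowSums(sm$velocity[sel, ]^2))
  expect_gt(mean(spd_m), mean(spd_w))
})

test_that("Newtonian peak speeds exceed Carreau peak speeds under
           traction driving", {
  # with a prescribed-velocity inlet the flux is pinned and the law only
  # reshapes the profile; under traction driving the less viscous
  # Newtonian fluid runs faster
  m <- channel_mesh(0.68, 0.1)
  rn <- run_simulation(m, quick_config(
    inlet_mode = "traction",
    fluid = fluid_params(model = "newtonian", newtonian_mu = 0.0032),
    snapshots = TRUE))
  rc <- run_simulation(m, quick_config(inlet_mode = "traction",
                                       snapshots = TRUE))
  vn <- max(sqrt(rowSums(attr(rn, "snapshots")$diastole$velocity^2)))
  vc <- max(sqrt(rowSums(attr(rc, "snapshots")$diastole$velocity^2)))
  expect_gt(vn, vc)
})

test_that("experiment outputs carry provenance and autoplot methods work", {
  tab <- memo("grid_struct",
              bc_model_grid(quick_config(), h = 0.13,
                            models = "carreau", bcs = "windkessel"))
  expect_false(is.null(attr(tab, "provenance")$config_hash))
  m <- channel_mesh(0.68, 0.1)
  res <- run_simulation(m, quick_config())
  expect_s3_class(ggplot2::autoplot(res), "ggplot")
  expect_s3_class(ggplot2::autoplot(ffr_from_series(res)[[1]]), "ggplot")
  expect_s3_class(ggplot2::autoplot(m), "ggplot")
  gl <- glance(res)
  expect_lt(gl$mass_defect_rel, 1e-6)
  expect_s3_class(tidy(res), "tbl_df")
})
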