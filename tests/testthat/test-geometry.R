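test_that("a one-branch tree is a tagged rectangle", {
  dom <- channel_domain(length = 5, diameter = 0.3)
  m <- mesh(dom, 0.1)
  expect_setequal(unique(m$boundary$tag), c("inlet", "wall", "outlet_1"))
  expect_equal(n_outlets(dom), 1L)
  # rectangle corners
  expect_equal(range(m$vertices[, 1]), c(0, 5))
  expect_equal(range(m$vertices[, 2]), c(-0.15, 0.15))
})

test_that("the packaged tree has four tagged outlets and a computed
           longest branch", {
  dom <- coronary_tree_domain()
  expect_equal(n_outlets(dom), 4L)
  m <- mesh(dom, 0.11)
  expect_setequal(grep("^outlet_", unique(m$boundary$tag), value = TRUE),
                  paste0("outlet_", 1:4))
  lt <- longest_terminal(dom)
  expect_equal(lt$branch_id, 4L) # the 5.5 cm branch
})

test_that("crossing branches are rejected", {
  br <- data.frame(
    id = 1:3, parent = c(NA, 1, 1),
    attach = c(NA, "left", "right"),
    # children turned sharply towards each other so their strips overlap
    angle = c(0, -70, 70) * pi / 180,
    length = c(2, 3, 3), diameter = c(0.4, 0.3, 0.3))
  expect_error(build_tree(tree_spec(br)), "cross")
})

test_that("stenosis narrows the lumen by exactly (1 - degree) at the
           throat", {
  dom <- channel_domain(diameter = 0.3, degree = 0.68, sensor = FALSE)
  w_min <- 2 * min(vffr:::branch_halfwidth(dom, 1,
                                           seq(0, 4, length.out = 4001)))
  expect_equal(w_min, (1 - 0.68) * 0.3, tolerance = 1e-10)
  # exactness across the admissible degree range
  for (deg in c(0.1, 0.3, 0.56, 0.8, 0.95)) {
    d2 <- channel_domain(diameter = 0.3, degree = deg, sensor = FALSE)
    expect_equal(2 * vffr:::branch_halfwidth(d2, 1, 1.5), (1 - deg) * 0.3,
                 tolerance = 1e-12)
  }
})

test_that("degree-zero stenosis leaves the domain unchanged", {
  dom <- build_tree(tree_spec(data.frame(id = 1, parent = NA, attach = NA,
                                         angle = 0, length = 4,
                                         diameter = 0.3)))
  dom2 <- apply_stenosis(dom, stenosis_spec(1, 1.5, 0.8, 0))
  expect_identical(dom2, dom)
})

test_that("invalid stenoses are rejected", {
  dom <- channel_domain(sensor = FALSE)
  expect_error(stenosis_spec(1, 1.5, 0.8, 1), "degree")
  expect_error(apply_stenosis(dom, stenosis_spec(1, 3.9, 0.8, 0.5)),
               "outside")
  # overlapping the bifurcation of a child branch
  tr <- coronary_tree_domain(lesions = FALSE)
  expect_error(apply_stenosis(tr, stenosis_spec(4, 0.2, 0.4, 0.5)),
               "bifurcation")
})

test_that("sensor disk sits 1 cm beyond the lesion at D_ref/10", {
  dom <- channel_domain(degree = 0.68, lesion_center = 1.5)
  sn <- dom$sensors[[1]]
  expect_equal(sn$s, 2.5)
  expect_equal(sn$diameter, 0.3 / 10)
  # the clinical wire in a 0.35 cm branch is a 0.035 cm disk
  d2 <- channel_domain(diameter = 0.35, degree = 0.5)
  expect_equal(d2$sensors[[1]]$diameter, 0.035)
})

test_that("inadmissible sensor placements error", {
  expect_error(channel_domain(degree = 0.68, normal_offset = 0.2),
               "placement")
  # inside the throat the lumen is too narrow for the disk
  dom <- channel_domain(degree = 0.9, sensor = FALSE)
  expect_error(place_sensor(dom, sensor_spec(1, arclength_offset_from_lesion = 0)),
               "placement")
})
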