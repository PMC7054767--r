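# FFR estimator: probe sampling, cycle means, running average, and the
# clinical classification.

test_that("aortic box sampling is the arithmetic nodal mean", {
  m <- channel_mesh(0.68, 0.1)
  # uniform field
  expect_equal(sample_aortic(m, rep(7.3, nrow(m$vertices))), 7.3)
  # linear-in-x field: the symmetric box mean is the centre value
  p_lin <- 5 + 2 * m$vertex_meta$s
  expect_equal(sample_aortic(m, p_lin), 5 + 2 * 1, tolerance = 1e-9)
  # brute-force enumeration oracle
  idx <- aortic_box_vertices(m, probe_spec())
  p <- rnorm(nrow(m$vertices))
  expect_equal(sample_aortic(m, p), sum(p[idx]) / length(idx))
  # a band centred between two station rows contains no vertices
  expect_error(aortic_box_vertices(m, probe_spec(arclength = 1.049,
                                                 half_width = 1e-9)),
               "empty aortic box")
})

test_that("sensor contour sampling averages the hole boundary nodes", {
  m <- channel_mesh(0.68, 0.1)
  expect_equal(sample_distal(m, rep(4.2, nrow(m$vertices))), 4.2)
  expect_error(sample_distal(m, rep(1, nrow(m$vertices)), "sensor_9"),
               "no boundary")
  # nodal mean vs line-integral (length-weighted) mean on a smooth field
  p <- 3 + 10 * m$vertices[, 1] + 6 * m$vertices[, 2]
  sel <- m$boundary$tag == "sensor_1"
  e1 <- m$boundary$v1[sel]; e2 <- m$boundary$v2[sel]
  len <- sqrt(rowSums((m$vertices[e1, , drop = FALSE] -
                         m$vertices[e2, , drop = FALSE])^2))
  line_mean <- sum(len * (p[e1] + p[e2]) / 2) / sum(len)
  expect_lt(abs(sample_distal(m, p) - line_mean) / abs(line_mean), 0.02)
})

test_that("two sensors are sampled independently per tag", {
  m <- memo("treemesh_0.1", mesh(coronary_tree_domain(), 0.1))
  p <- m$vertices[, 1] # x-coordinate as a stand-in pressure
  s1 <- sample_distal(m, p, "sensor_1")
  s2 <- sample_distal(m, p, "sensor_2")
  expect_false(isTRUE(all.equal(s1, s2)))
})

test_that("cycle means follow the device-style rectangle quadrature", {
  expect_equal(cycle_mean(rep(3.3, 160), 1, 0.8, 5e-3), 3.3)
  tt <- seq_len(160) * 5e-3
  expect_equal(cycle_mean(sin(2 * pi * tt / 0.8), 1, 0.8, 5e-3), 0,
               tolerance = 1e-12)
  # rectangle and trapezoid differ by O(dt) only
  tr <- 2 + cos(2 * pi * tt / 0.8)
  d <- abs(cycle_mean(tr, 1, 0.8, 5e-3) -
             cycle_mean(tr, 1, 0.8, 5e-3, method = "trapezoid"))
  expect_lt(d, 5e-3)
  expect_error(cycle_mean(rep(1, 100), 2, 0.8, 5e-3), "cover")
})

test_that("running-average FFR reproduces its reference per-cycle tables", {
  # finest grid: per-cycle FFR -> running averages
  ffr_fine <- c(0.9608, 0.9220, 0.8271, 0.8993, 0.9013)
  spc <- 160L
  Pd <- rep(ffr_fine, each = spc)
  Pa <- rep(1, 5L * spc)
  rec <- compute_ffr(Pa * 100, Pd * 100, 5L, 0.8, 5e-3)
  expect_equal(round(rec$FFR_a, 4), c(0.9608, 0.9414, 0.9033, 0.9023, 0.9021))
  # coarsest grid: final running average
  ffr_coarse <- c(0.9803, 0.93115, 0.8538, 0.9179, 0.9203)
  rec2 <- compute_ffr(Pa * 100, rep(ffr_coarse, each = spc) * 100,
                      5L, 0.8, 5e-3)
  expect_equal(round(rec2$FFR_a[5], 4), 0.9207)
})

test_that("FFR_a satisfies the cumulative-mean recursion", {
  set.seed(42)
  f <- runif(8, 0.6, 1)
  rec <- compute_ffr(rep(1, 8 * 100), rep(f, each = 100), 8L, 0.8, 8e-3)
  for (k in 2:8) {
    expect_equal(rec$FFR_a[k],
                 ((k - 1) * rec$FFR_a[k - 1] + rec$FFR[k]) / k,
                 tolerance = 1e-14)
  }
})

test_that("identical traces give unit FFR; bad traces error", {
  x <- 80 + sin(seq_len(320) / 10)
  rec <- compute_ffr(x, x, 2L, 0.8, 5e-3)
  expect_equal(rec$FFR, c(1, 1))
  expect_error(compute_ffr(-x, x, 2L, 0.8, 5e-3), "nonpositive")
})

test_that("a lesion-free channel keeps FFR_a above 0.95", {
  expect_gt(channel_ffr_a(0), 0.95)
})

test_that("probe traces are cycle-periodic once the flow settles", {
  res <- tree_run("windkessel")
  df <- as.data.frame(res)
  c4 <- df$Pa[df$cycle == 4]; c5 <- df$Pa[df$cycle == 5]
  expect_lt(sqrt(sum((c5 - c4)^2)) / sqrt(sum(c5^2)), 0.05)
})

test_that("clinical classification respects both cutoff modes", {
  expect_equal(as.character(classify_ffr(0.74)), "significant")
  expect_equal(as.character(classify_ffr(0.76)), "gray_zone")
  expect_equal(as.character(classify_ffr(0.85)), "nonsignificant")
  expect_equal(as.character(classify_ffr(c(0.74, 0.76), cutoffs = 0.75)),
               c("significant", "nonsignificant"))
  expect_error(classify_ffr(-0.1))
})

test_that("tidy and glance summarize FFR records", {
  f <- c(0.97, 0.93, 0.90, 0.90, 0.90)
  rec <- compute_ffr(rep(1, 500), rep(f, each = 100), 5L, 0.8, 8e-3)
  td <- tidy(rec)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("cycle", "Pa_mean", "Pdistal_mean", "FFR", "FFR_a",
                     "class"))
  gl <- glance(rec)
  expect_equal(gl$FFR_a, rec$FFR_a[5])
  expect_true(is.factor(gl$class))
})
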