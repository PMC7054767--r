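test_that("refinement strictly increases the element count", {
  dom <- coronary_tree_domain()
  m1 <- mesh(dom, 0.12)
  m2 <- mesh(dom, 0.06)
  expect_gt(nrow(m2$triangles), nrow(m1$triangles))
  expect_gt(nrow(m2$vertices), nrow(m1$vertices))
})

test_that("triangulations are conforming, positive and fully tagged", {
  m <- mesh(channel_domain(degree = 0.68), 0.1)
  v <- m$vertices; tr <- m$triangles
  area <- 0.5 * ((v[tr[, 2], 1] - v[tr[, 1], 1]) * (v[tr[, 3], 2] - v[tr[, 1], 2]) -
                   (v[tr[, 2], 2] - v[tr[, 1], 2]) * (v[tr[, 3], 1] - v[tr[, 1], 1]))
  expect_true(all(area > 0))
  expect_gt(m$quality_min, 0.02)
  # every vertex is used, every boundary edge carries exactly one tag
  expect_setequal(sort(unique(as.integer(tr))), seq_len(nrow(v)))
  ed <- rbind(tr[, 1:2], tr[, 2:3], tr[, c(3, 1)])
  key <- paste(pmin(ed[, 1], ed[, 2]), pmax(ed[, 1], ed[, 2]))
  bkey <- names(table(key))[table(key) == 1L]
  expect_setequal(bkey, paste(pmin(m$boundary$v1, m$boundary$v2),
                              pmax(m$boundary$v1, m$boundary$v2)))
})

test_that("sensor hole has >= 8 edges and near-circular perimeter", {
  m <- mesh(channel_domain(degree = 0.68), 0.1)
  sp <- m$boundary[m$boundary$tag == "sensor_1", ]
  expect_gte(nrow(sp), 8L)
  len <- sum(sqrt(rowSums((m$vertices[sp$v1, , drop = FALSE] -
                             m$vertices[sp$v2, , drop = FALSE])^2)))
  expect_lt(abs(len - pi * 0.03) / (pi * 0.03), 0.05)
})

test_that("too-coarse meshes abort with a throat diagnostic", {
  dom <- channel_domain(degree = 0.68, sensor = FALSE)
  expect_error(mesh(dom, 0.8), "too coarse")
})

test_that("mesh_for_vertices approximates a target grid", {
  dom <- coronary_tree_domain(lesions = 2L)
  m <- mesh_for_vertices(dom, 1478, h0 = 0.1)
  expect_lt(abs(nrow(m$vertices) - 1478) / 1478, 0.35)
})

test_that("MSH round-trip preserves coordinates, connectivity, tags and
           metadata", {
  m <- mesh(channel_domain(degree = 0.68), 0.1)
  f <- withr::local_tempfile(fileext = ".msh")
  write_mesh(m, f)
  m2 <- read_mesh(f)
  expect_equal(m2$vertices, m$vertices)
  expect_equal(m2$triangles, m$triangles)
  key <- function(b) sort(paste(pmin(b$v1, b$v2), pmax(b$v1, b$v2), b$tag))
  expect_identical(key(m2$boundary), key(m$boundary))
  expect_equal(m2$vertex_meta$s, m$vertex_meta$s)
  expect_equal(m2$h, m$h)
})

test_that("malformed mesh files are rejected", {
  m <- mesh(channel_domain(degree = 0.68), 0.12)
  f <- withr::local_tempfile(fileext = ".msh")
  write_mesh(m, f)
  # unknown tag name
  txt <- gsub('"wall"', '"lateral"', readLines(f))
  f2 <- withr::local_tempfile(fileext = ".msh")
  writeLines(txt, f2)
  expect_error(read_mesh(f2), "unknown boundary tag")
  # untagged boundary: drop all line elements
  txt <- readLines(f)
  i0 <- grep("^\\$Elements", txt); i1 <- grep("^\\$EndElements", txt)
  body <- txt[(i0 + 2):(i1 - 1)]
  keep <- body[!grepl("^[0-9]+ 1 ", body)]
  txt2 <- c(txt[1:i0], length(keep), keep, txt[i1:length(txt)])
  f3 <- withr::local_tempfile(fileext = ".msh")
  writeLines(txt2, f3)
  expect_error(read_mesh(f3), "untagged boundary")
  # empty mesh
  f4 <- withr::local_tempfile(fileext = ".msh")
  writeLines(c("$MeshFormat", "2.2 0 8", "$EndMeshFormat",
               '$PhysicalNames', "1", '1 1 "wall"', "$EndPhysicalNames",
               "$Nodes", "0", "$EndNodes",
               "$Elements", "0", "$EndElements"), f4)
  expect_error(read_mesh(f4), "empty mesh")
})

test_that("VTU snapshots are written", {
  m <- mesh(channel_domain(degree = 0.68), 0.12)
  f <- withr::local_tempfile(fileext = ".vtu")
  write_vtu(m, f, point_data = list(pressure = seq_len(nrow(m$vertices)),
                                    velocity = matrix(1, nrow(m$vertices), 2)))
  txt <- readLines(f)
  expect_true(any(grepl("UnstructuredGrid", txt)))
  expect_true(any(grepl('Name="pressure"', txt)))
})
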