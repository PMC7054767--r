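#' Parametric coronary-tree specification
#'
#' Describes a 2D branching channel network: a root (inlet) branch plus
#' children attached by Y-splits at their parent's end. Each branch is a
#' straight centerline segment with a reference diameter `D_ref`; a child
#' attaches to one half (`"left"` or `"right"`, looking along the flow) of
#' its parent's end cross-section and its lumen blends smoothly from that
#' half-width to its own diameter over roughly one parent diameter.
#'
#' @param branches Data frame with one row per branch and columns
#'   `id` (integer, 1..n, root first), `parent` (integer, `NA` for the
#'   root), `attach` (`"left"`/`"right"`, `NA` for the root), `angle`
#'   (radians; direction change relative to the parent direction, or the
#'   absolute direction for the root; positive = counter-clockwise),
#'   `length` (cm) and `diameter` (cm).
#' @param origin Root start point, cm.
#' @return An object of class `tree_spec`.
#' @examples
#' tree_spec(data.frame(id = 1, parent = NA, attach = NA, angle = 0,
#'                      length = 5, diameter = 0.3))
#' @export
tree_spec <- function(branches, origin = c(0, 0)) {
  b <- as.data.frame(branches)
  need <- c("id", "parent", "attach", "angle", "length", "diameter")
  if (!all(need %in% names(b))) {
    stop("branches must have columns: ", paste(need, collapse = ", "))
  }
  if (any(b$diameter <= 0)) stop("branch diameters must be > 0")
  if (any(b$length <= 0)) stop("branch lengths must be > 0")
  if (sum(is.na(b$parent)) != 1L) stop("exactly one root (inlet) branch required")
  root <- b$id[is.na(b$parent)]
  kids <- split(b$id[!is.na(b$parent)], b$parent[!is.na(b$parent)])
  if (any(lengths(kids) != 2L)) {
    stop("each non-terminal branch must have exactly 0 or 2 children (Y-splits)")
  }
  for (p in names(kids)) {
    at <- b$attach[match(kids[[p]], b$id)]
    if (!setequal(at, c("left", "right"))) {
      stop("the two children of branch ", p, " must attach 'left' and 'right'")
    }
  }
  terminals <- setdiff(b$id, as.integer(names(kids)))
  if (length(terminals) < 1L) stop("need at least one outlet branch")
  structure(list(branches = b, origin = as.numeric(origin), root = root),
            class = "tree_spec")
}

#' Stenosis specification
#'
#' A smooth symmetric cosine narrowing of the lumen: over the segment of
#' length `length` centred at `center_arclength`, the local width is scaled
#' by `1 - degree * (1 + cos(pi * xi)) / 2` with `xi` the signed position in
#' `[-1, 1]` across the segment, so the minimum width `(1 - degree) * D_ref`
#' is attained exactly at the centre and the narrowing joins the healthy
#' wall with zero slope.
#'
#' @param branch_id Branch carrying the lesion.
#' @param center_arclength Lesion centre along the branch, cm.
#' @param length Lesion length, cm.
#' @param degree Fractional diameter reduction, in `[0, 1)`.
#' @return An object of class `stenosis_spec`.
#' @export
stenosis_spec <- function(branch_id, center_arclength, length, degree) {
  if (!(degree >= 0 && degree < 1)) stop("stenosis degree must be in [0, 1)")
  if (!(length > 0)) stop("stenosis length must be > 0")
  structure(list(branch_id = as.integer(branch_id),
                 center_arclength = center_arclength,
                 length = length, degree = degree),
            class = "stenosis_spec")
}

#' Sensor-disk specification
#'
#' The pressure-wire transducer, modelled as a rigid no-slip disk of
#' diameter `D_ref / 10` (clinical 0.014-inch wire at the 1/10 size ratio)
#' placed `arclength_offset_from_lesion` (default 1 cm) downstream of a
#' lesion centre, at the centre of the cross-section unless offset.
#'
#' @param branch_id Branch carrying the sensor.
#' @param arclength_offset_from_lesion Distance beyond the lesion centre,
#'   cm.
#' @param normal_offset Displacement across the flow (towards the left
#'   wall when positive), cm.
#' @param tangential_offset Displacement along the flow, cm.
#' @param diameter Disk diameter, cm; `NULL` means `D_ref / 10` of the
#'   carrying branch.
#' @param lesion Index of the lesion (within the domain's stenosis list)
#'   the sensor refers to; `NULL` picks the lesion on `branch_id`.
#' @param absolute_arclength If set, anchor the disk at this arclength
#'   (cm) instead of relative to a lesion — e.g. for healthy reference
#'   geometries.
#' @return An object of class `sensor_spec`.
#' @export
sensor_spec <- function(branch_id, arclength_offset_from_lesion = 1,
                        normal_offset = 0, tangential_offset = 0,
                        diameter = NULL, lesion = NULL,
                        absolute_arclength = NULL) {
  structure(list(branch_id = as.integer(branch_id),
                 arclength_offset_from_lesion = arclength_offset_from_lesion,
                 normal_offset = normal_offset,
                 tangential_offset = tangential_offset,
                 diameter = diameter, lesion = lesion,
                 absolute_arclength = absolute_arclength),
            class = "sensor_spec")
}

rot2 <- function(th) matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
perp_left <- function(d) c(-d[2], d[1])
smoothstep <- function(t) {
  t <- pmin(pmax(t, 0), 1)
  t * t * (3 - 2 * t)
}

# Resolve the parametric spec into per-branch geometry records.
resolve_tree <- function(spec) {
  b <- spec$branches
  n <- nrow(b)
  res <- vector("list", n)
  names(res) <- as.character(b$id)
  # process parents before children
  done <- character(0)
  queue <- spec$root
  while (length(queue)) {
    id <- queue[1L]; queue <- queue[-1L]
    row <- b[b$id == id, ]
    if (is.na(row$parent)) {
      dir <- c(cos(row$angle), sin(row$angle))
      start <- spec$origin
      cross0 <- perp_left(dir)
      hw_start <- row$diameter / 2
      blend_len <- 0
    } else {
      pb <- res[[as.character(row$parent)]]
      dir <- as.numeric(rot2(row$angle) %*% pb$dir)
      n_hat <- pb$cross_end
      c_e <- pb$start + pb$L * pb$dir
      side <- if (row$attach == "left") 1 else -1
      start <- c_e + side * (pb$D / 4) * n_hat
      cross0 <- n_hat
      hw_start <- pb$D / 4
      blend_len <- pb$D
    }
    res[[as.character(id)]] <- list(
      id = id, parent = row$parent, attach = row$attach,
      start = start, dir = dir / sqrt(sum(dir^2)), L = row$length,
      D = row$diameter, hw_start = hw_start, blend_len = blend_len,
      cross0 = cross0,
      cross_end = perp_left(dir / sqrt(sum(dir^2))),
      children = b$id[!is.na(b$parent) & b$parent == id]
    )
    done <- c(done, as.character(id))
    queue <- c(queue, b$id[!is.na(b$parent) & b$parent == id])
  }
  terminals <- b$id[vapply(res, function(x) length(x$children) == 0L, logical(1))[as.character(b$id)]]
  for (k in seq_along(terminals)) {
    res[[as.character(terminals[k])]]$outlet_id <- k
  }
  attr(res, "bfs") <- done
  res
}

# Baseline (lesion-free) half-width of a branch at arclength s.
branch_halfwidth0 <- function(br, s) {
  if (br$blend_len <= 0) return(rep(br$D / 2, length(s)))
  g <- smoothstep(s / br$blend_len)
  br$hw_start + (br$D / 2 - br$hw_start) * g
}

# Stenosis width factor (product over lesions on the branch).
stenosis_factor <- function(stenoses, branch_id, s) {
  f <- rep(1, length(s))
  for (st in stenoses) {
    if (st$branch_id != branch_id) next
    xi <- (s - st$center_arclength) / (st$length / 2)
    inside <- abs(xi) < 1
    f[inside] <- f[inside] * (1 - st$degree * (1 + cos(pi * xi[inside])) / 2)
  }
  f
}

branch_halfwidth <- function(domain, branch_id, s) {
  br <- domain$tree[[as.character(branch_id)]]
  branch_halfwidth0(br, s) * stenosis_factor(domain$stenoses, branch_id, s)
}

# Cross-section direction (unit, pointing "left") at arclength s.
branch_crossdir <- function(br, s) {
  nc <- perp_left(br$dir)
  if (br$blend_len <= 0) return(matrix(nc, length(s), 2, byrow = TRUE))
  g <- smoothstep(s / br$blend_len)
  m <- cbind((1 - g) * br$cross0[1] + g * nc[1],
             (1 - g) * br$cross0[2] + g * nc[2])
  m / sqrt(rowSums(m^2))
}

branch_center <- function(br, s) {
  cbind(br$start[1] + s * br$dir[1], br$start[2] + s * br$dir[2])
}

# Sampled wall polylines of one branch (for intersection checks / plotting).
branch_walls <- function(domain, id, ds = NULL) {
  br <- domain$tree[[as.character(id)]]
  if (is.null(ds)) ds <- br$D / 3
  s <- unique(c(seq(0, br$L, by = ds), br$L))
  ctr <- branch_center(br, s)
  m <- branch_crossdir(br, s)
  hw <- branch_halfwidth(domain, id, s)
  list(left = ctr + m * hw, right = ctr - m * hw, s = s)
}

seg_intersect <- function(p1, p2, q1, q2) {
  d1 <- p2 - p1; d2 <- q2 - q1
  den <- d1[1] * d2[2] - d1[2] * d2[1]
  if (abs(den) < 1e-14) return(FALSE)
  w <- q1 - p1
  t <- (w[1] * d2[2] - w[2] * d2[1]) / den
  u <- (w[1] * d1[2] - w[2] * d1[1]) / den
  t > 1e-9 && t < 1 - 1e-9 && u > 1e-9 && u < 1 - 1e-9
}

check_no_crossing <- function(domain) {
  ids <- names(domain$tree)
  walls <- lapply(ids, function(id) branch_walls(domain, as.integer(id)))
  names(walls) <- ids
  segs <- list()
  for (id in ids) {
    for (side in c("left", "right")) {
      pl <- walls[[id]][[side]]
      for (k in seq_len(nrow(pl) - 1L)) {
        segs[[length(segs) + 1L]] <- list(a = pl[k, ], b = pl[k + 1L, ],
                                          branch = id)
      }
    }
  }
  ns <- length(segs)
  for (i in seq_len(ns - 1L)) {
    for (j in seq((i + 1L), ns)) {
      si <- segs[[i]]; sj <- segs[[j]]
      if (si$branch == sj$branch) next
      if (seg_intersect(si$a, si$b, sj$a, sj$b)) {
        stop("geometry error: branches ", si$branch, " and ", sj$branch,
             " cross")
      }
    }
  }
  invisible(TRUE)
}

#' Build a tagged planar domain from a tree specification
#'
#' Resolves the parametric tree into branch geometry, checks that no two
#' branches cross, and returns a `planar_domain` carrying the tree, an
#' (initially empty) lesion list and sensor list. Boundary tags are
#' `inlet` (root entry), `outlet_k` (one per terminal branch, 1-based in
#' branch-id order), `sensor_m` (disk contours) and `wall` elsewhere.
#'
#' @param spec A [tree_spec()].
#' @return An object of class `planar_domain`.
#' @export
build_tree <- function(spec) {
  stopifnot(inherits(spec, "tree_spec"))
  tree <- resolve_tree(spec)
  domain <- structure(list(spec = spec, tree = tree, stenoses = list(),
                           sensors = list()),
                      class = "planar_domain")
  check_no_crossing(domain)
  domain
}

#' Number of outlets of a domain
#' @param domain A `planar_domain`.
#' @return Integer count of terminal branches.
#' @export
n_outlets <- function(domain) {
  sum(vapply(domain$tree, function(b) length(b$children) == 0L, logical(1)))
}

#' Longest terminal branch
#'
#' The terminal branch with the greatest centreline arclength (used for the
#' mixed outlet boundary condition, where this branch is traction free).
#'
#' @param domain A `planar_domain`.
#' @return List with `branch_id` and `outlet_id`.
#' @export
longest_terminal <- function(domain) {
  term <- Filter(function(b) length(b$children) == 0L, domain$tree)
  lens <- vapply(term, function(b) b$L, numeric(1))
  b <- term[[which.max(lens)]]
  list(branch_id = b$id, outlet_id = b$outlet_id)
}

#' Narrow a branch with a stenosis
#'
#' Applies the cosine narrowing of a [stenosis_spec()] to the domain. A
#' degree-zero lesion leaves the domain unchanged. The lesion segment must
#' lie inside the branch and clear of the bifurcation blend regions.
#'
#' @param domain A `planar_domain`.
#' @param s A [stenosis_spec()].
#' @return The updated `planar_domain`.
#' @export
apply_stenosis <- function(domain, s) {
  stopifnot(inherits(domain, "planar_domain"), inherits(s, "stenosis_spec"))
  if (s$degree == 0) return(domain)
  br <- domain$tree[[as.character(s$branch_id)]]
  if (is.null(br)) stop("no branch ", s$branch_id)
  lo <- s$center_arclength - s$length / 2
  hi <- s$center_arclength + s$length / 2
  if (lo < 0 || hi > br$L) stop("stenosis segment extends outside branch")
  if (lo < br$blend_len) {
    stop("stenosis overlaps the bifurcation at the branch entrance")
  }
  if (length(br$children) > 0L && hi > br$L - 1e-9) {
    stop("stenosis overlaps the bifurcation at the branch end")
  }
  domain$stenoses[[length(domain$stenoses) + 1L]] <- s
  # lumen must stay open under the combined lesions
  sg <- seq(0, br$L, length.out = 400L)
  if (min(branch_halfwidth(domain, s$branch_id, sg)) <= 0) {
    stop("lumen closes: combined stenoses leave no open width")
  }
  domain
}

#' Place a sensor disk in the lumen
#'
#' Adds the pressure-sensor disk of a [sensor_spec()] as a hole (a no-slip
#' obstacle) in the carrying branch, by default 1 cm beyond the lesion
#' centre at the middle of the cross-section, with diameter `D_ref / 10`.
#' Errors if the disk would touch the wall or sit in a throat too narrow to
#' hold it.
#'
#' @param domain A `planar_domain`.
#' @param s A [sensor_spec()].
#' @return The updated `planar_domain`.
#' @export
place_sensor <- function(domain, s) {
  stopifnot(inherits(domain, "planar_domain"), inherits(s, "sensor_spec"))
  br <- domain$tree[[as.character(s$branch_id)]]
  if (is.null(br)) stop("no branch ", s$branch_id)
  if (!is.null(s$absolute_arclength)) {
    les <- NA_integer_
    s_c <- s$absolute_arclength + s$tangential_offset
  } else {
    les <- s$lesion
    if (is.null(les)) {
      on_branch <- which(vapply(domain$stenoses,
                                function(x) x$branch_id == s$branch_id,
                                logical(1)))
      if (length(on_branch) == 0L) {
        stop("no lesion on branch ", s$branch_id,
             " to place the sensor behind")
      }
      les <- on_branch[length(on_branch)]
    }
    st <- domain$stenoses[[les]]
    s_c <- st$center_arclength + s$arclength_offset_from_lesion +
      s$tangential_offset
  }
  d <- if (is.null(s$diameter)) br$D / 10 else s$diameter
  r <- d / 2
  if (s_c - r <= br$blend_len || s_c + r >= br$L) {
    stop("sensor placement error: disk outside branch interior")
  }
  span <- seq(s_c - r, s_c + r, length.out = 21L)
  hw_min <- min(branch_halfwidth(domain, s$branch_id, span))
  margin <- hw_min - (abs(s$normal_offset) + r)
  if (margin <= 0.25 * r) {
    stop("sensor placement error: disk intersects wall or stenosis throat")
  }
  rec <- list(branch_id = s$branch_id, s = s_c, n = s$normal_offset,
              diameter = d, lesion = les, spec = s)
  domain$sensors[[length(domain$sensors) + 1L]] <- rec
  domain
}

#' @export
print.planar_domain <- function(x, ...) {
  cat("<planar_domain> ", length(x$tree), " branches, ",
      n_outlets(x), " outlets, ", length(x$stenoses), " stenoses, ",
      length(x$sensors), " sensors\n", sep = "")
  invisible(x)
}

#' Packaged synthetic left-coronary-tree fixture
#'
#' A seven-branch planar tree (trunk, two intermediate branches, four
#' terminal branches) qualitatively mimicking a left coronary tree, with
#' the two study lesions (68% on a short terminal branch whose exit lies
#' close beyond the sensor, 56% at the entrance of the longest terminal
#' branch) and one sensor disk 1 cm beyond each lesion. Branch lengths and
#' diameters are declared package defaults in the 2-4 mm coronary caliber
#' range; they are not patient measurements.
#'
#' @param lesions Which of the two study lesions to add: `1` (68%, short
#'   terminal branch), `2` (56%, longest branch), both (default), or
#'   `integer(0)` / `FALSE` for a healthy tree.
#' @param sensors Add the sensor disk 1 cm beyond each included lesion?
#' @return A `planar_domain`.
#' @export
coronary_tree_domain <- function(lesions = c(1L, 2L), sensors = TRUE) {
  br <- data.frame(
    id       = 1:7,
    parent   = c(NA, 1, 1, 2, 2, 3, 3),
    attach   = c(NA, "right", "left", "right", "left", "left", "right"),
    angle    = c(0, -30, 60, -15, 40, 25, -22) * pi / 180,
    length   = c(2.0, 1.6, 1.4, 5.5, 2.0, 2.4, 2.0),
    diameter = c(0.40, 0.34, 0.32, 0.30, 0.28, 0.26, 0.26)
  )
  dom <- build_tree(tree_spec(br))
  if (isFALSE(lesions)) lesions <- integer(0)
  if (isTRUE(lesions)) lesions <- c(1L, 2L)
  specs <- list(
    # lesion 1: 68%, short terminal branch (sensor ends near the free exit)
    stenosis_spec(5, 0.70, 0.6, 0.68),
    # lesion 2: 56%, entrance of the longest terminal branch
    stenosis_spec(4, 0.80, 0.8, 0.56))
  for (li in lesions) {
    dom <- apply_stenosis(dom, specs[[li]])
    if (sensors) dom <- place_sensor(dom, sensor_spec(specs[[li]]$branch_id))
  }
  dom
}

#' Single-channel fixture
#'
#' A straight channel with an optional single cosine lesion and sensor:
#' the minimal geometry for solver benchmarks (Poiseuille flow) and for
#' severity and sensor-position studies where branch interaction is not
#' wanted.
#'
#' @param length Channel length, cm.
#' @param diameter Channel width, cm.
#' @param degree Stenosis degree (`0` for a plain channel).
#' @param lesion_center,lesion_length Lesion position/extent, cm.
#' @param sensor Place the sensor disk 1 cm beyond the lesion?
#' @param normal_offset,tangential_offset Sensor displacement, cm.
#' @return A `planar_domain`.
#' @export
channel_domain <- function(length = 4, diameter = 0.3, degree = 0,
                           lesion_center = 1.5, lesion_length = 0.8,
                           sensor = degree > 0, normal_offset = 0,
                           tangential_offset = 0) {
  br <- data.frame(id = 1, parent = NA, attach = NA, angle = 0,
                   length = length, diameter = diameter)
  dom <- build_tree(tree_spec(br))
  if (degree > 0) {
    dom <- apply_stenosis(dom, stenosis_spec(1, lesion_center, lesion_length,
                                             degree))
  }
  if (sensor) {
    sp <- if (degree > 0) {
      sensor_spec(1, normal_offset = normal_offset,
                  tangential_offset = tangential_offset)
    } else {
      # healthy reference: the disk sits where it would with a lesion
      sensor_spec(1, normal_offset = normal_offset,
                  tangential_offset = tangential_offset,
                  absolute_arclength = lesion_center + 1)
    }
    dom <- place_sensor(dom, sp)
  }
  dom
}
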