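# Structured triangulation of a planar_domain.
#
# Each branch is meshed as a mapped strip: cross-sections ("stations") along
# the centreline, nn equal intervals across the local lumen width.  At a
# bifurcation the two children start from the two halves of the parent's end
# cross-section and a 1-to-2 fan band restores the full across resolution,
# so the global triangulation is conforming.  A sensor disk is meshed as an
# O-grid: the grid cells of a small rectangular patch are removed and the
# annulus between the patch ring and the disk contour is filled with
# geometrically graded rings.

new_node_store <- function(cap = 4096L) {
  env <- new.env(parent = emptyenv())
  env$xy <- matrix(NA_real_, cap, 2)
  env$meta <- matrix(NA_real_, cap, 3) # branch, s, n
  env$n <- 0L
  env
}

add_nodes <- function(store, xy, branch, s, n_off) {
  k <- nrow(xy)
  while (store$n + k > nrow(store$xy)) {
    store$xy <- rbind(store$xy, matrix(NA_real_, nrow(store$xy), 2))
    store$meta <- rbind(store$meta, matrix(NA_real_, nrow(store$meta), 3))
  }
  idx <- store$n + seq_len(k)
  store$xy[idx, ] <- xy
  store$meta[idx, ] <- cbind(rep(branch, k), s, n_off)
  store$n <- store$n + k
  idx
}

# Station arclengths for one branch: base spacing h, graded down inside
# stenoses (proportionally to the remaining width) and near sensor disks
# (to resolve the O-grid patch).
branch_stations <- function(domain, id, h) {
  br <- domain$tree[[as.character(id)]]
  sens <- Filter(function(x) x$branch_id == id, domain$sensors)
  ds_at <- function(s) {
    f <- stenosis_factor(domain$stenoses, id, s)
    ds <- h * max(0.45, f)
    for (sn in sens) {
      r <- sn$diameter / 2
      if (abs(s - sn$s) < 2 * r + h) ds <- min(ds, max(1.5 * r, h / 5))
    }
    ds
  }
  s <- 0
  out <- 0
  while (TRUE) {
    step <- ds_at(s)
    if (s + step >= br$L - 1e-12) break
    s <- s + step
    out <- c(out, s)
  }
  if (br$L - out[length(out)] < 0.5 * ds_at(br$L)) {
    out[length(out)] <- br$L
  } else {
    out <- c(out, br$L)
  }
  out
}

station_nodes <- function(domain, id, s, nn) {
  br <- domain$tree[[as.character(id)]]
  ctr <- branch_center(br, s)[1, ]
  m <- branch_crossdir(br, s)[1, ]
  hw <- branch_halfwidth(domain, id, s)
  eta <- seq(-1, 1, length.out = nn + 1L)
  xy <- cbind(ctr[1] + eta * hw * m[1], ctr[2] + eta * hw * m[2])
  list(xy = xy, n_off = eta * hw)
}

tri_quality <- function(v, tr) {
  a <- v[tr[, 1], , drop = FALSE]
  b <- v[tr[, 2], , drop = FALSE]
  c_ <- v[tr[, 3], , drop = FALSE]
  l1 <- rowSums((b - a)^2); l2 <- rowSums((c_ - b)^2); l3 <- rowSums((a - c_)^2)
  area <- 0.5 * ((b[, 1] - a[, 1]) * (c_[, 2] - a[, 2]) -
                   (b[, 2] - a[, 2]) * (c_[, 1] - a[, 1]))
  4 * sqrt(3) * abs(area) / (l1 + l2 + l3)
}

quad_split <- function(a, b, c_, d, xy) {
  # split quad (a,b,c_,d) along the diagonal that maximizes the worst
  # triangle quality (robust against near-collinear corner layouts in the
  # O-grid annuli)
  s1 <- rbind(c(a, b, c_), c(a, c_, d))
  s2 <- rbind(c(a, b, d), c(b, c_, d))
  if (min(tri_quality(xy, s1)) >= min(tri_quality(xy, s2))) s1 else s2
}

#' Triangulate a planar domain
#'
#' Builds a conforming triangle mesh of the tree with `nn` intervals across
#' every lumen and along-centreline spacing `h` (cm), graded down inside
#' stenoses and around sensor disks. Sensor disks become polygonal holes
#' with at least 8 contour edges, connected to the surrounding grid by an
#' O-grid annulus.
#'
#' @param domain A `planar_domain`.
#' @param h Target element size along the centreline, cm.
#' @param nn Across-lumen interval count (even; default derived from `h`
#'   and the root diameter).
#' @param hole_rings Number of intermediate rings in the sensor annulus.
#' @param min_quality Minimum accepted triangle quality (1 = equilateral);
#'   below it meshing aborts with a diagnostic.
#' @return An object of class `mesh_domain`.
#' @export
mesh <- function(domain, h = 0.1, nn = NULL, hole_rings = 2L,
                 min_quality = 0.02) {
  stopifnot(inherits(domain, "planar_domain"), h > 0)
  root <- domain$tree[[which(vapply(domain$tree,
                                    function(b) is.na(b$parent), logical(1)))]]
  if (is.null(nn)) nn <- 2L * max(2L, as.integer(round(root$D / (2 * h))))
  if (nn %% 2L != 0L || nn < 4L) stop("nn must be even and >= 4")

  store <- new_node_store()
  tris <- vector("list", 256L); ntri <- 0L
  push_tris <- function(m) {
    ntri <<- ntri + 1L
    tris[[ntri]] <<- m
  }
  inlet_pairs <- NULL
  outlet_pairs <- list()
  sensor_pairs <- list()
  end_rows <- list()   # branch id -> node ids of its final station row

  ids <- attr(domain$tree, "bfs")
  if (is.null(ids)) ids <- names(domain$tree)
  # parents before children
  for (id_ch in ids) {
    id <- as.integer(id_ch)
    br <- domain$tree[[id_ch]]
    stations <- branch_stations(domain, id, h)
    # stenosis resolution check
    for (st in domain$stenoses) {
      if (st$branch_id != id) next
      inside <- sum(abs(stations - st$center_arclength) < st$length / 2)
      if (inside < 4L) {
        stop("h too coarse to resolve the stenosis throat on branch ", id,
             " (", inside, " stations inside the lesion; need >= 4). ",
             "Reduce h below ", signif(st$length / 8, 3), " cm.")
      }
    }
    rows <- vector("list", length(stations) + 1L)
    row_s <- numeric(length(stations) + 1L)
    nrows <- 0L
    if (is.na(br$parent)) {
      first_regular <- 1L
    } else {
      pe <- end_rows[[as.character(br$parent)]]
      half <- if (br$attach == "left") pe[(nn / 2 + 1L):(nn + 1L)] else pe[1:(nn / 2 + 1L)]
      nrows <- nrows + 1L
      rows[[nrows]] <- half
      row_s[nrows] <- 0
      stations <- stations[-1L] # s = 0 handled by the parent row
      first_regular <- 2L
    }
    for (s in stations) {
      sn <- station_nodes(domain, id, s, nn)
      idx <- add_nodes(store, sn$xy, id, s, sn$n_off)
      nrows <- nrows + 1L
      rows[[nrows]] <- idx
      row_s[nrows] <- s
    }
    rows <- rows[seq_len(nrows)]
    row_s <- row_s[seq_len(nrows)]
    end_rows[[id_ch]] <- rows[[nrows]]

    # sensor O-grid patches: pick index rectangles of removed cells
    removed <- matrix(FALSE, nrows - 1L, nn) # band i (rows i,i+1) x cell j
    patches <- list()
    for (sidx in seq_along(domain$sensors)) {
      sn <- domain$sensors[[sidx]]
      if (sn$branch_id != id) next
      r <- sn$diameter / 2
      ctr_xy <- branch_center(br, sn$s)[1, ] +
        sn$n * branch_crossdir(br, sn$s)[1, ]
      i0 <- max(which(row_s <= sn$s - 1.2 * r))
      i1 <- min(which(row_s >= sn$s + 1.2 * r))
      i0 <- max(i0, first_regular)
      while (i1 - i0 < 2L) { # at least 2 station intervals in the patch
        if (i1 < nrows) i1 <- i1 + 1L
        else if (i0 > first_regular) i0 <- i0 - 1L
        else stop("sensor placement error: disk too close to the branch end for h")
      }
      if (i1 > nrows) {
        stop("sensor placement error: disk too close to the branch end for h")
      }
      hw_c <- branch_halfwidth(domain, id, sn$s)
      eta <- seq(-1, 1, length.out = nn + 1L)
      eta_lo <- (sn$n - 1.2 * r) / hw_c
      eta_hi <- (sn$n + 1.2 * r) / hw_c
      j0 <- max(which(eta <= max(-1, eta_lo)))
      j1 <- min(which(eta >= min(1, eta_hi))) - 1L # cell index upper bound
      j0 <- j0 - 1L # to 0-based cell index lower bound
      if (j1 - j0 < 2L) { # widen to at least 2 cells
        if (j0 > 0L) j0 <- j0 - 1L else j1 <- j1 + 1L
        if (j1 - j0 < 2L) j1 <- min(nn, j1 + 1L)
      }
      j0 <- max(0L, j0); j1 <- min(nn, j1)
      # widen the station span until the patch is roughly square, so the
      # O-grid ring stays close to circular
      n_extent <- (j1 - j0) * 2 * hw_c / nn
      repeat {
        s_extent <- row_s[i1] - row_s[i0]
        if (s_extent >= 0.8 * n_extent) break
        grew <- FALSE
        if (i1 < nrows) { i1 <- i1 + 1L; grew <- TRUE }
        if (row_s[i1] - row_s[i0] < 0.8 * n_extent && i0 > first_regular) {
          i0 <- i0 - 1L; grew <- TRUE
        }
        if (!grew) break
      }
      if (any(removed[i0:(i1 - 1L), (j0 + 1L):j1])) {
        stop("sensor placement error: overlapping sensor patches")
      }
      removed[i0:(i1 - 1L), (j0 + 1L):j1] <- TRUE
      patches[[length(patches) + 1L]] <-
        list(i0 = i0, i1 = i1, j0 = j0, j1 = j1, center = ctr_xy, r = r,
             sensor = sidx, s = sn$s)
    }

    # transition fan band (children only)
    if (first_regular == 2L) {
      coarse <- rows[[1L]]; fine <- rows[[2L]]
      for (jc in seq_len(nn / 2) - 1L) {
        c0 <- coarse[jc + 1L]; c1 <- coarse[jc + 2L]
        f0 <- fine[2L * jc + 1L]; f1 <- fine[2L * jc + 2L]; f2 <- fine[2L * jc + 3L]
        push_tris(rbind(c(c0, f0, f1), c(c0, f1, c1), c(c1, f1, f2)))
      }
    }
    # regular bands
    for (i in seq(first_regular, nrows - 1L)) {
      ra <- rows[[i]]; rb <- rows[[i + 1L]]
      for (j in seq_len(nn)) {
        if (removed[i, j]) next
        a <- ra[j]; b <- rb[j]; c_ <- rb[j + 1L]; d <- ra[j + 1L]
        push_tris(quad_split(a, b, c_, d, store$xy))
      }
    }
    # O-grid annuli
    for (pt in patches) {
      ring <- c(rows[[pt$i0]][(pt$j0 + 1L):(pt$j1 + 1L)],
                vapply(seq(pt$i0 + 1L, pt$i1), function(i) rows[[i]][pt$j1 + 1L],
                       numeric(1)),
                rev(rows[[pt$i1]][(pt$j0 + 1L):(pt$j1)]),
                rev(vapply(seq(pt$i0 + 1L, pt$i1 - 1L),
                           function(i) rows[[i]][pt$j0 + 1L], numeric(1))))
      ring <- as.integer(ring)
      m <- length(ring)
      rel <- store$xy[ring, , drop = FALSE] -
        matrix(pt$center, m, 2, byrow = TRUE)
      dist <- sqrt(rowSums(rel^2))
      if (any(dist <= pt$r * 1.05)) {
        stop("sensor placement error: disk does not fit inside the grid patch")
      }
      # unwrapped ring-node angles; circle nodes equally spaced in angle,
      # matched monotonically to the ring loop (no twist)
      th <- atan2(rel[, 2], rel[, 1])
      dth <- c(0, diff(th))
      dth <- ((dth + pi) %% (2 * pi)) - pi
      thu <- th[1] + cumsum(dth)
      closing <- ((th[1] - thu[m] + pi) %% (2 * pi)) - pi
      orient <- sign(sum(dth) + closing)
      th_eq <- thu[1] + (seq_len(m) - 1L) * orient * 2 * pi / m
      circ_xy <- cbind(pt$center[1] + pt$r * cos(th_eq),
                       pt$center[2] + pt$r * sin(th_eq))
      n_loc <- (circ_xy - branch_center(br, pt$s)[rep(1, m), , drop = FALSE])
      mdir <- branch_crossdir(br, pt$s)[1, ]
      circ <- add_nodes(store, circ_xy, id, pt$s,
                        n_loc[, 1] * mdir[1] + n_loc[, 2] * mdir[2])
      # enough rings that each geometric band grows by at most ~2x
      n_rings <- max(hole_rings, ceiling(log(max(dist) / pt$r) / log(2)))
      rings <- vector("list", n_rings + 2L)
      rings[[1L]] <- circ
      for (q in seq_len(n_rings)) {
        frac <- q / (n_rings + 1L)
        rad <- pt$r * (dist / pt$r)^frac
        ang <- th_eq + frac * (thu - th_eq)
        xy <- cbind(pt$center[1] + rad * cos(ang),
                    pt$center[2] + rad * sin(ang))
        rings[[q + 1L]] <- add_nodes(store, xy, id, pt$s, rep(NA_real_, m))
      }
      rings[[n_rings + 2L]] <- ring
      for (q in seq_len(n_rings + 1L)) {
        ia <- rings[[q]]; ib <- rings[[q + 1L]]
        for (k in seq_len(m)) {
          k2 <- if (k == m) 1L else k + 1L
          push_tris(quad_split(ia[k], ib[k], ib[k2], ia[k2], store$xy))
        }
      }
      sensor_pairs[[pt$sensor]] <- cbind(circ, circ[c(2:m, 1L)])
    }

    if (is.na(br$parent)) {
      r1 <- rows[[1L]]
      inlet_pairs <- cbind(r1[-length(r1)], r1[-1L])
    }
    if (length(br$children) == 0L) {
      re <- rows[[nrows]]
      outlet_pairs[[br$outlet_id]] <- cbind(re[-length(re)], re[-1L])
    }
  }

  v <- store$xy[seq_len(store$n), , drop = FALSE]
  meta <- store$meta[seq_len(store$n), , drop = FALSE]
  tr <- do.call(rbind, tris[seq_len(ntri)])
  # drop nodes orphaned by removed patch cells and renumber
  used <- sort(unique(as.integer(tr)))
  if (length(used) < nrow(v)) {
    remap <- integer(nrow(v))
    remap[used] <- seq_along(used)
    v <- v[used, , drop = FALSE]
    meta <- meta[used, , drop = FALSE]
    tr[] <- remap[tr]
    if (!is.null(inlet_pairs)) inlet_pairs[] <- remap[inlet_pairs]
    outlet_pairs <- lapply(outlet_pairs, function(p) {p[] <- remap[p]; p})
    sensor_pairs <- lapply(sensor_pairs, function(p) {
      if (is.null(p)) return(NULL)
      p[] <- remap[p]; p
    })
  }
  # enforce CCW orientation
  area2 <- (v[tr[, 2], 1] - v[tr[, 1], 1]) * (v[tr[, 3], 2] - v[tr[, 1], 2]) -
    (v[tr[, 2], 2] - v[tr[, 1], 2]) * (v[tr[, 3], 1] - v[tr[, 1], 1])
  if (any(abs(area2) < 1e-14)) stop("degenerate triangle produced; reduce h")
  flip <- area2 < 0
  tr[flip, c(2L, 3L)] <- tr[flip, c(3L, 2L)]

  q <- tri_quality(v, tr)
  if (min(q) < min_quality) {
    stop("mesh quality ", signif(min(q), 3), " below threshold ",
         min_quality, "; geometry under-resolved at h = ", h)
  }

  # boundary edges: edges adjacent to exactly one triangle
  ed <- rbind(tr[, c(1L, 2L)], tr[, c(2L, 3L)], tr[, c(3L, 1L)])
  key <- paste(pmin(ed[, 1], ed[, 2]), pmax(ed[, 1], ed[, 2]))
  tab <- table(key)
  bkey <- names(tab)[tab == 1L]
  is_b <- key %in% bkey
  bed <- ed[is_b, , drop = FALSE]

  pair_keys <- function(p) paste(pmin(p[, 1], p[, 2]), pmax(p[, 1], p[, 2]))
  tag <- rep("wall", nrow(bed))
  bk <- paste(pmin(bed[, 1], bed[, 2]), pmax(bed[, 1], bed[, 2]))
  if (!is.null(inlet_pairs)) tag[bk %in% pair_keys(inlet_pairs)] <- "inlet"
  for (k in seq_along(outlet_pairs)) {
    tag[bk %in% pair_keys(outlet_pairs[[k]])] <- paste0("outlet_", k)
  }
  for (k in seq_along(sensor_pairs)) {
    if (is.null(sensor_pairs[[k]])) next
    tag[bk %in% pair_keys(sensor_pairs[[k]])] <- paste0("sensor_", k)
  }

  structure(list(
    vertices = v,
    triangles = tr,
    boundary = data.frame(v1 = bed[, 1], v2 = bed[, 2], tag = tag,
                          stringsAsFactors = FALSE),
    vertex_meta = data.frame(branch = meta[, 1], s = meta[, 2], n = meta[, 3]),
    h = h, nn = nn,
    n_outlets = length(outlet_pairs),
    n_sensors = length(sensor_pairs),
    domain = domain,
    quality_min = min(q)
  ), class = "mesh_domain")
}

#' @export
print.mesh_domain <- function(x, ...) {
  cat("<mesh_domain> ", nrow(x$vertices), " vertices, ",
      nrow(x$triangles), " triangles, h = ", x$h, " cm, ",
      x$n_outlets, " outlets, ", x$n_sensors, " sensor holes\n", sep = "")
  invisible(x)
}

#' Mesh a domain to an approximate vertex count
#'
#' Chooses `h` by secant iteration on the (smooth, monotone) vertex-count
#' response so the mesh has roughly `target_nv` vertices — the handle used
#' by the convergence driver to emulate grids of prescribed size.
#'
#' @param domain A `planar_domain`.
#' @param target_nv Desired vertex count.
#' @param h0 Starting element size, cm.
#' @param iters Secant iterations.
#' @param ... Passed to [mesh()].
#' @return A `mesh_domain`.
#' @export
mesh_for_vertices <- function(domain, target_nv, h0 = 0.1, iters = 3L, ...) {
  h <- h0
  m <- mesh(domain, h, ...)
  for (k in seq_len(iters)) {
    # vertex count scales roughly as 1/h^2 once nn tracks h
    h <- h * sqrt(nrow(m$vertices) / target_nv)
    m <- mesh(domain, h, ...)
    if (abs(nrow(m$vertices) - target_nv) / target_nv < 0.15) break
  }
  m
}
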