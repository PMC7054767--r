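# Taylor-Hood function spaces on a mesh_domain: P2 (vertices + edge
# midpoints) vector velocities, P1 (vertex) pressures.  Precomputes the
# edge table, boundary dof sets per tag, and the boundary integral vectors
# b_tag[i] = int_Gamma phi_i n ds used for outlet fluxes and normal-traction
# loads.  All stored coordinates are SI (meters).

#' Build Taylor-Hood spaces on a mesh
#'
#' @param m A `mesh_domain`.
#' @return An object of class `fem_spaces` with the edge table, dof counts
#'   (`n2` velocity scalar dofs, `n1` pressure dofs), per-tag boundary dof
#'   sets, boundary normal-integral vectors, and inlet profile geometry.
#' @export
fem_spaces <- function(m) {
  stopifnot(inherits(m, "mesh_domain"))
  tr <- m$triangles
  nv <- nrow(m$vertices)
  nt <- nrow(tr)
  # unique edges; local edge k is opposite local vertex k
  e_all <- rbind(tr[, c(2L, 3L)], tr[, c(3L, 1L)], tr[, c(1L, 2L)])
  key <- paste(pmin(e_all[, 1], e_all[, 2]), pmax(e_all[, 1], e_all[, 2]))
  uk <- !duplicated(key)
  edges <- e_all[uk, , drop = FALSE]
  edge_id <- match(key, key[uk])
  tri_edges <- matrix(edge_id, nt, 3L)
  ne <- nrow(edges)
  n2 <- nv + ne
  n1 <- nv

  coords_m <- m$vertices * M_PER_CM
  mid_m <- (coords_m[edges[, 1], , drop = FALSE] +
              coords_m[edges[, 2], , drop = FALSE]) / 2

  # adjacent triangle of each edge (first one seen), for outward normals
  adj <- integer(ne)
  tid <- rep(seq_len(nt), 3L)
  adj[edge_id[uk]] <- tid[uk]

  centroids <- (coords_m[tr[, 1], , drop = FALSE] +
                  coords_m[tr[, 2], , drop = FALSE] +
                  coords_m[tr[, 3], , drop = FALSE]) / 3

  # map boundary records to edge ids
  bkey <- paste(pmin(m$boundary$v1, m$boundary$v2),
                pmax(m$boundary$v1, m$boundary$v2))
  bedge <- match(bkey, paste(pmin(edges[, 1], edges[, 2]),
                             pmax(edges[, 1], edges[, 2])))
  if (anyNA(bedge)) stop("boundary records do not match the triangulation")

  tags <- sort(unique(m$boundary$tag))
  p1 <- coords_m[edges[bedge, 1], , drop = FALSE]
  p2 <- coords_m[edges[bedge, 2], , drop = FALSE]
  ev <- p2 - p1
  len <- sqrt(rowSums(ev^2))
  nrm <- cbind(ev[, 2], -ev[, 1]) / len
  mid <- (p1 + p2) / 2
  toc <- centroids[adj[bedge], , drop = FALSE] - mid
  flip <- rowSums(nrm * toc) > 0
  nrm[flip, ] <- -nrm[flip, ]

  bvec <- list()
  dofs <- list()
  for (tg in tags) {
    sel <- which(m$boundary$tag == tg)
    b <- numeric(2L * n2)
    vs <- integer(0)
    for (k in sel) {
      e <- bedge[k]
      va <- edges[e, 1]; vb <- edges[e, 2]; md <- nv + e
      L <- len[k]; nx <- nrm[k, 1]; ny <- nrm[k, 2]
      b[va] <- b[va] + L / 6 * nx
      b[vb] <- b[vb] + L / 6 * nx
      b[md] <- b[md] + 2 * L / 3 * nx
      b[n2 + va] <- b[n2 + va] + L / 6 * ny
      b[n2 + vb] <- b[n2 + vb] + L / 6 * ny
      b[n2 + md] <- b[n2 + md] + 2 * L / 3 * ny
      vs <- c(vs, va, vb, md)
    }
    bvec[[tg]] <- b
    dofs[[tg]] <- sort(unique(vs))
  }

  # inlet profile geometry: inward direction and transverse offsets
  inlet <- NULL
  if ("inlet" %in% tags) {
    sel <- which(m$boundary$tag == "inlet")
    n_in <- -colSums(nrm[sel, , drop = FALSE] * len[sel]) # inward, weighted
    n_in <- n_in / sqrt(sum(n_in^2))
    t_in <- c(-n_in[2], n_in[1])
    wdofs <- dofs[["inlet"]]
    pos <- rbind(coords_m, mid_m)[wdofs, , drop = FALSE]
    xi <- as.numeric(pos %*% t_in)
    xi <- xi - (max(xi) + min(xi)) / 2
    width <- sum(len[sel])
    inlet <- list(dir = n_in, tangent = t_in, width = width,
                  dofs = wdofs, xi = xi)
  }

  sensor_tags <- grep("^sensor_", tags, value = TRUE)
  outlet_tags <- grep("^outlet_", tags, value = TRUE)
  outlet_tags <- outlet_tags[order(as.integer(sub("outlet_", "", outlet_tags)))]

  structure(list(
    mesh = m, nv = nv, ne = ne, n2 = n2, n1 = n1,
    edges = edges, tri_edges = tri_edges,
    coords_m = coords_m, mid_m = mid_m,
    tags = tags, bvec = bvec, dofs = dofs,
    inlet = inlet, outlet_tags = outlet_tags, sensor_tags = sensor_tags
  ), class = "fem_spaces")
}

#' @export
print.fem_spaces <- function(x, ...) {
  cat("<fem_spaces> P2/P1: ", 2L * x$n2, " velocity + ", x$n1,
      " pressure dofs\n", sep = "")
  invisible(x)
}

#' Boundary flux of a velocity field
#'
#' Computes `int_Gamma u . n ds` over a tagged boundary with the outward
#' normal, so inflow across the inlet is negative. Reported per unit depth
#' in cm^3/s (1 cm slab convention).
#'
#' @param spaces A [fem_spaces()] object.
#' @param u Velocity dof vector (SI, length `2 * n2`) or a `flow_state`.
#' @param tag Boundary tag, e.g. `"outlet_1"`.
#' @return Signed flux, cm^3/s.
#' @export
boundary_flux <- function(spaces, u, tag) {
  stopifnot(inherits(spaces, "fem_spaces"))
  if (inherits(u, "flow_state")) u <- u$u
  b <- spaces$bvec[[tag]]
  if (is.null(b)) stop("unknown boundary tag: ", tag)
  sum(b * u) * 1e4 # m^2/s -> cm^2/s, per-cm-depth convention
}

# Weak divergence residual max |B u| / scale, for incompressibility checks.
divergence_residual <- function(B, u) {
  r <- as.numeric(B %*% u)
  max(abs(r)) / max(max(abs(u)), 1e-300)
}
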