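# Gmsh MSH 2.2 ASCII and VTU (ASCII XML) mesh exchange.  Boundary tags are
# stored as 1D physical groups named after the tag; per-vertex branch
# metadata travels in a $NodeData block so probe positions survive a
# round-trip.

valid_tag <- function(tag) {
  grepl("^(inlet|wall|outlet_[0-9]+|sensor_[0-9]+)$", tag)
}

#' Write a mesh in Gmsh MSH 2.2 ASCII format
#'
#' Boundary edges are written as 2-node line elements carrying the physical
#' group of their tag; triangles carry a single `domain` group. Vertex
#' metadata (branch id, arclength, transverse offset) is appended as a
#' `$NodeData` block so that [read_mesh()] restores it.
#'
#' @param m A `mesh_domain`.
#' @param path Output file path (`.msh`).
#' @return `path`, invisibly.
#' @export
write_mesh <- function(m, path) {
  stopifnot(inherits(m, "mesh_domain"))
  tags <- sort(unique(m$boundary$tag))
  tag_id <- setNames(seq_along(tags), tags)
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(c(...), con)
  w("$MeshFormat", "2.2 0 8", "$EndMeshFormat")
  w("$PhysicalNames", as.character(length(tags) + 1L))
  for (t in tags) w(sprintf('1 %d "%s"', tag_id[[t]], t))
  w(sprintf('2 %d "domain"', length(tags) + 1L))
  w("$EndPhysicalNames")
  nv <- nrow(m$vertices)
  w("$Nodes", as.character(nv))
  w(sprintf("%d %.17g %.17g 0", seq_len(nv), m$vertices[, 1], m$vertices[, 2]))
  w("$EndNodes")
  nb <- nrow(m$boundary); nt <- nrow(m$triangles)
  w("$Elements", as.character(nb + nt))
  w(sprintf("%d 1 2 %d %d %d %d", seq_len(nb), tag_id[m$boundary$tag],
            tag_id[m$boundary$tag], m$boundary$v1, m$boundary$v2))
  w(sprintf("%d 2 2 %d %d %d %d %d", nb + seq_len(nt),
            length(tags) + 1L, length(tags) + 1L,
            m$triangles[, 1], m$triangles[, 2], m$triangles[, 3]))
  w("$EndElements")
  if (!is.null(m$vertex_meta)) {
    w("$NodeData", "1", '"vertex_meta"', "1", sprintf("%.17g", m$h),
      "3", "0", "3", as.character(nv))
    w(sprintf("%d %.17g %.17g %.17g", seq_len(nv),
              m$vertex_meta$branch, m$vertex_meta$s, m$vertex_meta$n))
    w("$EndNodeData")
  }
  invisible(path)
}

#' Read a mesh from Gmsh MSH 2.2 ASCII format
#'
#' Restores a `mesh_domain` written by [write_mesh()] (or produced by any
#' tool using the same tag vocabulary). Every boundary edge of the
#' triangulation must be covered by a tagged line element, and tag names
#' must be `inlet`, `wall`, `outlet_<k>` or `sensor_<m>`.
#'
#' @param path Input file path.
#' @return A `mesh_domain` (without the parametric tree description).
#' @export
read_mesh <- function(path) {
  lines <- readLines(path)
  sect <- function(name) {
    i0 <- match(paste0("$", name), lines)
    i1 <- match(paste0("$End", name), lines)
    if (is.na(i0) || is.na(i1)) return(NULL)
    lines[(i0 + 1L):(i1 - 1L)]
  }
  pn <- sect("PhysicalNames")
  if (is.null(pn)) stop("mesh file has no physical names (tags)")
  pn <- pn[-1L]
  pm <- regmatches(pn, regexec('^([0-9]+) ([0-9]+) "(.*)"$', pn))
  pdim <- vapply(pm, function(x) as.integer(x[2]), integer(1))
  pid <- vapply(pm, function(x) as.integer(x[3]), integer(1))
  pname <- vapply(pm, function(x) x[4], character(1))
  bnames <- pname[pdim == 1L]
  if (length(bnames) && !all(valid_tag(bnames))) {
    stop("unknown boundary tag name(s): ",
         paste(bnames[!valid_tag(bnames)], collapse = ", "))
  }
  tag_of <- setNames(pname, pid)

  nd <- sect("Nodes")
  if (is.null(nd) || as.integer(nd[1L]) == 0L) stop("empty mesh: no nodes")
  nv <- as.integer(nd[1L])
  num <- utils::read.table(text = nd[-1L])
  v <- as.matrix(num[order(num[[1]]), 2:3])
  dimnames(v) <- NULL

  el <- sect("Elements")
  if (is.null(el) || as.integer(el[1L]) == 0L) stop("empty mesh: no elements")
  el <- el[-1L]
  parts <- strsplit(el, " +")
  type <- vapply(parts, function(x) as.integer(x[2]), integer(1))
  tri <- t(vapply(parts[type == 2L],
                  function(x) as.integer(utils::tail(x, 3L)), integer(3)))
  if (length(tri) == 0L) stop("empty mesh: no triangles")
  bl <- parts[type == 1L]
  bed <- t(vapply(bl, function(x) as.integer(utils::tail(x, 2L)), integer(2)))
  btag <- vapply(bl, function(x) {
    ntags <- as.integer(x[3])
    tag_of[[x[4]]]
  }, character(1))

  # every boundary edge of the triangulation must carry a tag
  ed <- rbind(tri[, c(1L, 2L)], tri[, c(2L, 3L)], tri[, c(3L, 1L)])
  key <- paste(pmin(ed[, 1], ed[, 2]), pmax(ed[, 1], ed[, 2]))
  tab <- table(key)
  need <- names(tab)[tab == 1L]
  have <- paste(pmin(bed[, 1], bed[, 2]), pmax(bed[, 1], bed[, 2]))
  if (!all(need %in% have)) {
    stop("untagged boundary: ", sum(!(need %in% have)),
         " boundary edge(s) carry no tag")
  }
  keep <- have %in% need
  bed <- bed[keep, , drop = FALSE]
  btag <- btag[keep]

  meta <- NULL; h <- NA_real_
  ndat <- sect("NodeData")
  if (!is.null(ndat)) {
    nstr <- as.integer(ndat[1L])
    nreal <- as.integer(ndat[1L + nstr + 1L])
    if (nreal >= 1L) h <- as.numeric(ndat[1L + nstr + 2L])
    nint <- as.integer(ndat[1L + nstr + 1L + nreal + 1L])
    skip <- 1L + nstr + 1L + nreal + 1L + nint
    rows <- utils::read.table(text = ndat[-seq_len(skip)])
    rows <- rows[order(rows[[1]]), ]
    meta <- data.frame(branch = rows[[2]], s = rows[[3]], n = rows[[4]])
  }
  outlets <- unique(btag[grepl("^outlet_", btag)])
  sensors <- unique(btag[grepl("^sensor_", btag)])
  structure(list(
    vertices = v,
    triangles = tri,
    boundary = data.frame(v1 = bed[, 1], v2 = bed[, 2], tag = btag,
                          stringsAsFactors = FALSE),
    vertex_meta = meta,
    h = h, nn = NA_integer_,
    n_outlets = length(outlets),
    n_sensors = length(sensors),
    domain = NULL,
    quality_min = NA_real_
  ), class = "mesh_domain")
}

#' Write a VTU snapshot (ASCII)
#'
#' Unstructured-grid XML file with optional point data (e.g. `velocity`,
#' `pressure`) for inspection in ParaView.
#'
#' @param m A `mesh_domain`.
#' @param path Output path (`.vtu`).
#' @param point_data Named list of per-vertex data: vectors (scalars) or
#'   2-column matrices (written as 3-vectors with zero z).
#' @return `path`, invisibly.
#' @export
write_vtu <- function(m, path, point_data = list()) {
  stopifnot(inherits(m, "mesh_domain"))
  nv <- nrow(m$vertices); nt <- nrow(m$triangles)
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(c(...), con)
  w('<?xml version="1.0"?>',
    '<VTKFile type="UnstructuredGrid" version="0.1" byte_order="LittleEndian">',
    "<UnstructuredGrid>",
    sprintf('<Piece NumberOfPoints="%d" NumberOfCells="%d">', nv, nt))
  w("<Points>",
    '<DataArray type="Float64" NumberOfComponents="3" format="ascii">')
  w(sprintf("%.10g %.10g 0", m$vertices[, 1], m$vertices[, 2]))
  w("</DataArray>", "</Points>")
  if (length(point_data)) {
    w("<PointData>")
    for (nm in names(point_data)) {
      d <- point_data[[nm]]
      if (is.matrix(d)) {
        w(sprintf('<DataArray type="Float64" Name="%s" NumberOfComponents="3" format="ascii">', nm))
        w(sprintf("%.10g %.10g 0", d[, 1], d[, 2]))
      } else {
        w(sprintf('<DataArray type="Float64" Name="%s" format="ascii">', nm))
        w(sprintf("%.10g", d))
      }
      w("</DataArray>")
    }
    w("</PointData>")
  }
  w("<Cells>",
    '<DataArray type="Int32" Name="connectivity" format="ascii">')
  w(sprintf("%d %d %d", m$triangles[, 1] - 1L, m$triangles[, 2] - 1L,
            m$triangles[, 3] - 1L))
  w("</DataArray>",
    '<DataArray type="Int32" Name="offsets" format="ascii">')
  w(sprintf("%d", 3L * seq_len(nt)))
  w("</DataArray>", '<DataArray type="UInt8" Name="types" format="ascii">')
  w(rep("5", nt))
  w("</DataArray>", "</Cells>", "</Piece>", "</UnstructuredGrid>", "</VTKFile>")
  invisible(path)
}
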