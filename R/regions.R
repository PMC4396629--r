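#' Facial region (ROI) definitions
#'
#' A region definition names 9 facial segments — forehead (FH), left/right
#' eye (LE/RE), nose (N), left/right cheek (LC/RC), mouth (M, which absorbs
#' the chin), and left/right neck (LN/RN) — each as an ordered list of
#' fiducial names forming a closed polygon in the (phi, z) plane of the
#' cylindrical parameterization.
#'
#' @param polygons named list; each element a character vector (>= 3 fiducial
#'   names) tracing a closed polygon.
#' @return An object of class `region_definition`.
#' @export
region_definition <- function(polygons) {
  if (is.null(names(polygons)) || anyDuplicated(names(polygons))) {
    stop_facesim("regions must be uniquely named", class = "facesim_input_error")
  }
  for (nm in names(polygons)) {
    if (length(polygons[[nm]]) < 3) {
      stop_facesim("region ", nm, " needs >= 3 polygon vertices",
        class = "facesim_input_error"
      )
    }
  }
  structure(list(polygons = polygons), class = "region_definition")
}

#' @export
print.region_definition <- function(x, ...) {
  cat("<region_definition> ", length(x$polygons), " ROIs: ",
    paste(names(x$polygons), collapse = ", "), "\n",
    sep = ""
  )
  invisible(x)
}

#' Read / write region configuration files
#'
#' Plain-text format, one ROI per line: `NAME: fid1,fid2,fid3,...`.
#'
#' @param path file path.
#' @return [read_regions()] returns a [region_definition()].
#' @export
read_regions <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  polys <- list()
  for (ln in lines) {
    parts <- strsplit(ln, ":", fixed = TRUE)[[1]]
    if (length(parts) != 2) {
      stop_facesim("malformed region line: ", ln, class = "facesim_io_error")
    }
    polys[[trimws(parts[1])]] <- trimws(strsplit(parts[2], ",", fixed = TRUE)[[1]])
  }
  region_definition(polys)
}

#' @param regions a [region_definition()].
#' @rdname read_regions
#' @export
write_regions <- function(regions, path) {
  lines <- vapply(
    names(regions$polygons),
    function(nm) paste0(nm, ": ", paste(regions$polygons[[nm]], collapse = ",")),
    character(1)
  )
  writeLines(lines, path)
  invisible(path)
}

# Even-odd point-in-polygon test, vectorized over points. Points exactly on a
# polygon edge count as inside (deterministic tie-break).
point_in_polygon <- function(px, py, poly_x, poly_y, tol = 1e-12) {
  k <- length(poly_x)
  inside <- rep(FALSE, length(px))
  on_edge <- rep(FALSE, length(px))
  scale <- max(abs(c(poly_x, poly_y)), 1)
  tol <- tol * scale
  j <- k
  for (i in seq_len(k)) {
    xi <- poly_x[i]; yi <- poly_y[i]
    xj <- poly_x[j]; yj <- poly_y[j]
    # on-edge: collinear and within the segment bounding box
    cross <- (xj - xi) * (py - yi) - (yj - yi) * (px - xi)
    seg_len <- sqrt((xj - xi)^2 + (yj - yi)^2)
    col <- abs(cross) <= tol * max(seg_len, 1) &
      px >= pmin(xi, xj) - tol & px <= pmax(xi, xj) + tol &
      py >= pmin(yi, yj) - tol & py <= pmax(yi, yj) + tol
    on_edge <- on_edge | col
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside | on_edge
}

#' ROI vertex selection on a mesh
#'
#' Selects the vertices whose (phi, z) projection falls inside the union of
#' the named ROI polygons, and splits them into interior and boundary sets.
#' The boundary consists of selected vertices that either have a mesh-edge
#' neighbor outside the selection or lie on the mesh's topological boundary
#' (so that a selection covering the whole mesh still has Dirichlet rows).
#'
#' @param mesh a [surface_mesh()].
#' @param fids a [fiducial_set()] resolving the polygon vertex names.
#' @param regions a [region_definition()].
#' @param roi_names character vector of ROI names to take the union of.
#' @param tilt_deg tilt for the cylindrical projection (default 10).
#' @return list with integer vectors `interior` and `boundary` (disjoint;
#'   together they form the ROI vertex set).
#' @export
roi_vertex_set <- function(mesh, fids, regions, roi_names, tilt_deg = 10) {
  unknown <- setdiff(roi_names, names(regions$polygons))
  if (length(unknown) > 0) {
    stop_facesim(
      "unknown ROI name(s): ", paste(unknown, collapse = ", "),
      class = "facesim_region_error"
    )
  }
  cyl <- to_cylindrical(mesh, tilt_deg)
  sel <- rep(FALSE, nrow(mesh$vertices))
  for (nm in roi_names) {
    poly <- fid_coords(fids, regions$polygons[[nm]])
    pc <- to_cylindrical(poly, tilt_deg)
    in_poly <- point_in_polygon(cyl$phi, cyl$z, pc$phi, pc$z)
    if (!any(in_poly)) {
      stop_facesim(
        "ROI ", nm, " selects no vertices on this mesh",
        class = "facesim_region_error"
      )
    }
    sel <- sel | in_poly
  }
  ids <- which(sel)
  edges <- mesh_edges(mesh)
  # selected vertices adjacent to an unselected vertex
  a_in <- sel[edges[, 1]]
  b_in <- sel[edges[, 2]]
  bnd <- unique(c(edges[a_in & !b_in, 1], edges[!a_in & b_in, 2]))
  bnd <- union(bnd, intersect(ids, mesh_boundary_vertices(mesh)))
  boundary <- sort(as.integer(bnd))
  interior <- setdiff(ids, boundary)
  list(interior = as.integer(interior), boundary = boundary)
}
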