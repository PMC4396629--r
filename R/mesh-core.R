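#' Colored triangle surface mesh
#'
#' Container for a simplicial triangle surface with per-vertex RGB color, the
#' basic face representation used throughout the package. Coordinates are in
#' millimetres; colors are floats in `[0, 1]` (8-bit channels are rescaled on
#' file I/O).
#'
#' @param vertices numeric `n x 3` matrix of vertex coordinates (mm).
#' @param faces integer `m x 3` matrix of 1-based vertex indices.
#' @param colors optional numeric `n x 3` matrix of RGB in `[0, 1]`; if
#'   `NULL`, vertices default to mid-gray `0.5`.
#' @param validate if `TRUE` (default) check the simplicial-surface
#'   invariants (indices in range, no degenerate faces, every edge shared by
#'   at most two faces).
#' @return An object of class `surface_mesh`: a list with elements
#'   `vertices`, `faces`, `colors`.
#' @export
surface_mesh <- function(vertices, faces, colors = NULL, validate = TRUE) {
  vertices <- as_matrix3(vertices, "vertices")
  faces <- as_matrix3(faces, "faces")
  storage.mode(faces) <- "integer"
  n <- nrow(vertices)
  if (is.null(colors)) {
    colors <- matrix(0.5, n, 3)
  }
  colors <- as_matrix3(colors, "colors")
  if (nrow(colors) != n) {
    stop_facesim("colors must have one row per vertex", class = "facesim_input_error")
  }
  mesh <- structure(list(vertices = vertices, faces = faces, colors = colors),
    class = "surface_mesh"
  )
  if (validate) validate_surface_mesh(mesh)
  mesh
}

validate_surface_mesh <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  if (!all(is.finite(v))) {
    stop_facesim("vertex coordinates must be finite", class = "facesim_input_error")
  }
  if (nrow(f) > 0) {
    if (min(f) < 1L || max(f) > nrow(v)) {
      stop_facesim("face indices out of range", class = "facesim_input_error")
    }
    degen <- f[, 1] == f[, 2] | f[, 2] == f[, 3] | f[, 1] == f[, 3]
    if (any(degen)) {
      stop_facesim(
        "face ", which(degen)[1], " repeats a vertex index",
        class = "facesim_input_error"
      )
    }
    cnt <- edge_face_counts(f, nrow(v))
    if (any(cnt > 2L)) {
      stop_facesim(
        "mesh is not a simplicial surface: an edge is shared by > 2 faces",
        class = "facesim_input_error"
      )
    }
  }
  if (any(mesh$colors < 0 | mesh$colors > 1)) {
    stop_facesim("colors must lie in [0, 1]", class = "facesim_input_error")
  }
  invisible(mesh)
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(
    "<surface_mesh> ", nrow(x$vertices), " vertices, ",
    nrow(x$faces), " faces\n",
    sep = ""
  )
  invisible(x)
}

# Undirected edge keys (pmin, pmax encoded) for a face matrix.
edge_keys <- function(faces, n) {
  a <- c(faces[, 1], faces[, 2], faces[, 3])
  b <- c(faces[, 2], faces[, 3], faces[, 1])
  lo <- pmin(a, b)
  hi <- pmax(a, b)
  (as.double(lo) - 1) * n + (as.double(hi) - 1)
}

edge_face_counts <- function(faces, n) {
  keys <- edge_keys(faces, n)
  table(keys)
}

#' Unique undirected edges of a mesh
#'
#' @param mesh a [surface_mesh()].
#' @return integer matrix with two columns (vertex index pairs, lo < hi).
#' @export
mesh_edges <- function(mesh) {
  f <- mesh$faces
  n <- nrow(mesh$vertices)
  if (nrow(f) == 0) {
    return(matrix(integer(0), 0, 2))
  }
  a <- c(f[, 1], f[, 2], f[, 3])
  b <- c(f[, 2], f[, 3], f[, 1])
  lo <- pmin(a, b)
  hi <- pmax(a, b)
  keys <- (as.double(lo) - 1) * n + (as.double(hi) - 1)
  keep <- !duplicated(keys)
  cbind(lo[keep], hi[keep])
}

# Vertex ids lying on the topological boundary (incident to an edge with a
# single adjacent face).
mesh_boundary_vertices <- function(mesh) {
  f <- mesh$faces
  n <- nrow(mesh$vertices)
  if (nrow(f) == 0) {
    return(integer(0))
  }
  a <- c(f[, 1], f[, 2], f[, 3])
  b <- c(f[, 2], f[, 3], f[, 1])
  lo <- pmin(a, b)
  hi <- pmax(a, b)
  keys <- (as.double(lo) - 1) * n + (as.double(hi) - 1)
  tab <- table(keys)
  single <- as.double(names(tab)[tab == 1L])
  if (length(single) == 0) {
    return(integer(0))
  }
  lo_b <- floor(single / n) + 1
  hi_b <- single - (lo_b - 1) * n + 1
  sort(unique(as.integer(c(lo_b, hi_b))))
}

# Area-weighted per-vertex unit normals.
vertex_normals <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  p1 <- v[f[, 1], , drop = FALSE]
  e1 <- v[f[, 2], , drop = FALSE] - p1
  e2 <- v[f[, 3], , drop = FALSE] - p1
  fn <- cbind(
    e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
    e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
    e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  )
  n <- matrix(0, nrow(v), 3)
  for (k in 1:3) {
    for (d in 1:3) {
      acc <- tapply(fn[, d], f[, k], sum)
      ids <- as.integer(names(acc))
      n[ids, d] <- n[ids, d] + acc
    }
  }
  len <- row_norms(n)
  len[len == 0] <- 1
  n / len
}

mesh_area <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  p1 <- v[f[, 1], , drop = FALSE]
  e1 <- v[f[, 2], , drop = FALSE] - p1
  e2 <- v[f[, 3], , drop = FALSE] - p1
  cr <- cbind(
    e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
    e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
    e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  )
  sum(row_norms(cr)) / 2
}

#' Linear 1-to-4 midpoint subdivision
#'
#' Splits every triangle into four using the three edge midpoints. Midpoint
#' position and color are the averages of the edge endpoints; shared edges
#' produce a single shared midpoint vertex, so the subdivided mesh has
#' `V + E` vertices and `4F` faces and the surface is preserved pointwise.
#'
#' @param mesh a [surface_mesh()].
#' @return the subdivided [surface_mesh()].
#' @export
subdivide_midpoint <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  n <- nrow(v)
  edges <- mesh_edges(mesh)
  ekey <- (as.double(edges[, 1]) - 1) * n + (as.double(edges[, 2]) - 1)
  mid_v <- (v[edges[, 1], , drop = FALSE] + v[edges[, 2], , drop = FALSE]) / 2
  mid_c <- (mesh$colors[edges[, 1], , drop = FALSE] +
    mesh$colors[edges[, 2], , drop = FALSE]) / 2

  edge_id <- function(a, b) {
    lo <- pmin(a, b)
    hi <- pmax(a, b)
    n + match((as.double(lo) - 1) * n + (as.double(hi) - 1), ekey)
  }
  mab <- edge_id(f[, 1], f[, 2])
  mbc <- edge_id(f[, 2], f[, 3])
  mca <- edge_id(f[, 3], f[, 1])
  new_f <- rbind(
    cbind(f[, 1], mab, mca),
    cbind(f[, 2], mbc, mab),
    cbind(f[, 3], mca, mbc),
    cbind(mab, mbc, mca)
  )
  surface_mesh(rbind(v, mid_v), new_f, rbind(mesh$colors, mid_c))
}

#' Named fiducial (landmark) point set
#'
#' Ordered map from landmark name to a 3D point (mm), with a role tag per
#' point. A complete modeling set has 61 entries (45 anthropometric + 16
#' outline points); a complete validation set has 10 (7 mid-face + 3
#' peripheral).
#'
#' @param points numeric `k x 3` matrix with unique rownames (the landmark
#'   names).
#' @param role character vector of length `k`, each `"modeling"` or
#'   `"validation"`.
#' @return An object of class `fiducial_set`.
#' @export
fiducial_set <- function(points, role) {
  points <- as.matrix(points)
  if (is.null(rownames(points)) || anyDuplicated(rownames(points))) {
    stop_facesim("fiducial points need unique rownames", class = "facesim_input_error")
  }
  if (!all(is.finite(points))) {
    stop_facesim("fiducial coordinates must be finite", class = "facesim_input_error")
  }
  storage.mode(points) <- "double"
  role <- as.character(role)
  if (length(role) == 1L) role <- rep(role, nrow(points))
  if (length(role) != nrow(points) || !all(role %in% c("modeling", "validation"))) {
    stop_facesim(
      "role must be 'modeling' or 'validation', one per point",
      class = "facesim_input_error"
    )
  }
  names(role) <- rownames(points)
  structure(list(points = points, role = role), class = "fiducial_set")
}

#' @export
print.fiducial_set <- function(x, ...) {
  cat(
    "<fiducial_set> ", sum(x$role == "modeling"), " modeling, ",
    sum(x$role == "validation"), " validation points\n",
    sep = ""
  )
  invisible(x)
}

#' Fiducial set accessors
#'
#' `fid_names()` lists landmark names (optionally by role); `fid_coords()`
#' returns coordinates for the requested names; `subset_fiducials()` takes a
#' named subset.
#'
#' @param fids a [fiducial_set()].
#' @param role optional role filter (`"modeling"`/`"validation"`).
#' @param names landmark names (`NULL` = all).
#' @return names, a coordinate matrix, or a [fiducial_set()] respectively.
#' @export
fid_names <- function(fids, role = NULL) {
  nm <- rownames(fids$points)
  if (!is.null(role)) nm <- nm[fids$role %in% role]
  nm
}

#' @rdname fid_names
#' @export
fid_coords <- function(fids, names = NULL) {
  if (is.null(names)) {
    return(fids$points)
  }
  missing <- setdiff(names, rownames(fids$points))
  if (length(missing) > 0) {
    stop_facesim(
      "fiducial point(s) not found: ", paste(missing, collapse = ", "),
      class = "facesim_landmark_error"
    )
  }
  fids$points[names, , drop = FALSE]
}

#' @rdname fid_names
#' @export
subset_fiducials <- function(fids, names) {
  fiducial_set(fid_coords(fids, names), fids$role[names])
}

#' Read / write fiducial CSV files
#'
#' The on-disk schema is `name,role,x_mm,y_mm,z_mm`.
#'
#' @param path file path.
#' @return [read_fiducials()] returns a [fiducial_set()].
#' @export
read_fiducials <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "role", "x_mm", "y_mm", "z_mm")
  if (!all(need %in% names(df))) {
    stop_facesim(
      "fiducial CSV must have columns ", paste(need, collapse = ","),
      class = "facesim_io_error"
    )
  }
  pts <- as.matrix(df[, c("x_mm", "y_mm", "z_mm")])
  dimnames(pts) <- list(df$name, NULL)
  fiducial_set(pts, df$role)
}

#' @param fids a [fiducial_set()].
#' @rdname read_fiducials
#' @export
write_fiducials <- function(fids, path) {
  df <- data.frame(
    name = rownames(fids$points),
    role = unname(fids$role),
    x_mm = fids$points[, 1],
    y_mm = fids$points[, 2],
    z_mm = fids$points[, 3]
  )
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

translate_mesh <- function(mesh, t) {
  mesh$vertices <- sweep(mesh$vertices, 2, t, "+")
  mesh
}

translate_fiducials <- function(fids, t) {
  fids$points <- sweep(fids$points, 2, t, "+")
  fids
}

#' Align a face by its nose tip
#'
#' Rigidly translates mesh and fiducials so that the `nose_tip` fiducial lands
#' at (0, 0, 50) mm, which places the vertex centroid of a cropped face near
#' the origin and prepares the face for the cylindrical parameterization.
#'
#' @param mesh a [surface_mesh()].
#' @param fids a [fiducial_set()] containing a point named `nose_tip`.
#' @return list with elements `mesh` and `fids`, both translated.
#' @export
align_nose_tip <- function(mesh, fids) {
  nt <- fid_coords(fids, "nose_tip")[1, ]
  t <- c(0, 0, 50) - nt
  list(mesh = translate_mesh(mesh, t), fids = translate_fiducials(fids, t))
}

#' Cylindrical face parameterization
#'
#' Rotates points by `tilt_deg` about the left-right (x) axis so the forehead
#' moves backward, then maps them to cylindrical coordinates with the
#' cylinder axis the vertical line through the origin:
#' `rho = sqrt(x^2 + z^2)`, `phi = atan2(x, z)` (zero toward the face's depth
#' direction, branch cut at the back of the head), and height `= y`.
#'
#' @param x a [surface_mesh()] or an `n x 3` coordinate matrix, aligned with
#'   the nose near (0, 0, 50) mm.
#' @param tilt_deg forehead tilt in degrees (default 10).
#' @return An object of class `cylindrical_coords`: list with numeric vectors
#'   `rho` (radial, mm), `phi` (azimuth, radians in (-pi, pi]) and `z`
#'   (height, mm).
#' @export
to_cylindrical <- function(x, tilt_deg = 10) {
  v <- if (inherits(x, "surface_mesh")) x$vertices else as_matrix3(x)
  v <- v %*% t(rot_x(-tilt_deg))
  rho <- sqrt(v[, 1]^2 + v[, 3]^2)
  phi <- atan2(v[, 1], v[, 3])
  on_axis <- rho == 0
  if (any(on_axis)) {
    phi[on_axis] <- 0
    message(sum(on_axis), " vertex/vertices exactly on the cylinder axis; phi set to 0")
  }
  structure(list(rho = rho, phi = phi, z = v[, 2]), class = "cylindrical_coords")
}

#' Inverse cylindrical mapping
#'
#' @param cyl a `cylindrical_coords` object (or list with `rho`, `phi`, `z`).
#' @param tilt_deg the tilt used in [to_cylindrical()].
#' @return `n x 3` Cartesian coordinate matrix.
#' @export
from_cylindrical <- function(cyl, tilt_deg = 10) {
  v <- cbind(cyl$rho * sin(cyl$phi), cyl$z, cyl$rho * cos(cyl$phi))
  v %*% t(rot_x(tilt_deg))
}
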