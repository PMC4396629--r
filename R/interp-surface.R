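# Piecewise-linear interpolation of per-vertex values over a 2D-projected
# triangulation, used to resample a target face's radial coordinate and
# colors at arbitrary (phi, z) query points.
#
# The target mesh's own triangulation (projected to the (phi, z) plane) is
# the interpolant. Where the projection folds so that a query lies in more
# than one triangle (e.g. residual ear geometry), the triangle with the
# largest interpolated first value (rho, the outermost surface) wins. Queries
# falling in no triangle (outside the cropped face, or over an acquisition
# hole) take the value of the nearest projected vertex and are flagged.
#
# points: n x 2 projected vertex coordinates; faces: m x 3 indices;
# values: n x k per-vertex values (column 1 = rho when meshes are involved);
# query: q x 2. nn_scale rescales the two coordinates for the
# nearest-neighbor fill only, so that an azimuth in radians can be compared
# with a height in mm on an arc-length footing.
interp_on_triangulation <- function(points, faces, values, query,
                                    nn_scale = c(1, 1)) {
  values <- as.matrix(values)
  q <- nrow(query)
  out <- matrix(NA_real_, q, ncol(values))
  filled <- rep(FALSE, q)
  if (nrow(faces) == 0 || q == 0) {
    filled[] <- TRUE
  } else {
    x1 <- points[faces[, 1], 1]; y1 <- points[faces[, 1], 2]
    x2 <- points[faces[, 2], 1]; y2 <- points[faces[, 2], 2]
    x3 <- points[faces[, 3], 1]; y3 <- points[faces[, 3], 2]
    det <- (y2 - y3) * (x1 - x3) + (x3 - x2) * (y1 - y3)
    ok_tri <- abs(det) > 0

    # grid-bucket index over triangle bounding boxes
    bx0 <- pmin(x1, x2, x3); bx1 <- pmax(x1, x2, x3)
    by0 <- pmin(y1, y2, y3); by1 <- pmax(y1, y2, y3)
    xr <- range(points[, 1]); yr <- range(points[, 2])
    ext_x <- max(xr[2] - xr[1], 1e-9)
    ext_y <- max(yr[2] - yr[1], 1e-9)
    ncell <- max(1L, as.integer(floor(sqrt(nrow(faces)))))
    gx <- max(1L, as.integer(round(ncell * sqrt(ext_x / ext_y))))
    gy <- max(1L, as.integer(round(ncell * sqrt(ext_y / ext_x))))
    cell_x <- function(x) clamp(1L + as.integer(floor((x - xr[1]) / ext_x * gx)), 1L, gx)
    cell_y <- function(y) clamp(1L + as.integer(floor((y - yr[1]) / ext_y * gy)), 1L, gy)

    ix0 <- cell_x(bx0); ix1 <- cell_x(bx1)
    iy0 <- cell_y(by0); iy1 <- cell_y(by1)
    span <- (ix1 - ix0 + 1L) * (iy1 - iy0 + 1L)
    tri_rep <- rep.int(seq_len(nrow(faces)), span)
    cell_of <- integer(sum(span))
    pos <- 1L
    for (t in seq_len(nrow(faces))) {
      cs <- outer(ix0[t]:ix1[t], (iy0[t]:iy1[t] - 1L) * gx, `+`)
      cell_of[pos:(pos + length(cs) - 1L)] <- as.integer(cs)
      pos <- pos + length(cs)
    }
    ord <- order(cell_of)
    cell_sorted <- cell_of[ord]
    tri_sorted <- tri_rep[ord]
    counts <- tabulate(cell_sorted, nbins = gx * gy)
    starts <- cumsum(c(0L, counts))

    qc <- cell_x(query[, 1]) + (cell_y(query[, 2]) - 1L) * gx
    tol <- -1e-9
    for (i in seq_len(q)) {
      c_i <- qc[i]
      k <- counts[c_i]
      if (k == 0L) next
      cand <- tri_sorted[(starts[c_i] + 1L):(starts[c_i] + k)]
      cand <- cand[ok_tri[cand]]
      if (length(cand) == 0L) next
      px <- query[i, 1]; py <- query[i, 2]
      l1 <- ((y2[cand] - y3[cand]) * (px - x3[cand]) +
        (x3[cand] - x2[cand]) * (py - y3[cand])) / det[cand]
      l2 <- ((y3[cand] - y1[cand]) * (px - x3[cand]) +
        (x1[cand] - x3[cand]) * (py - y3[cand])) / det[cand]
      l3 <- 1 - l1 - l2
      hit <- which(l1 >= tol & l2 >= tol & l3 >= tol)
      if (length(hit) == 0L) next
      f_hit <- cand[hit]
      vals <- l1[hit] * values[faces[f_hit, 1], , drop = FALSE] +
        l2[hit] * values[faces[f_hit, 2], , drop = FALSE] +
        l3[hit] * values[faces[f_hit, 3], , drop = FALSE]
      pick <- which.max(vals[, 1])
      out[i, ] <- vals[pick, ]
      filled[i] <- FALSE
    }
    filled <- filled | !stats::complete.cases(out)
  }

  # nearest-neighbor extrapolation for misses
  miss <- which(filled)
  if (length(miss) > 0) {
    sc <- rep(nn_scale, length.out = 2)
    nn <- nearest_point_index(
      sweep(points, 2, sc, "*"),
      sweep(query[miss, , drop = FALSE], 2, sc, "*")
    )
    out[miss, ] <- values[nn, , drop = FALSE]
  }
  list(values = out, filled = filled)
}

# Index of the nearest of `points` (n x d) for each row of `query` (q x d),
# brute force in chunks.
nearest_point_index <- function(points, query) {
  q <- nrow(query)
  res <- integer(q)
  chunk <- max(1L, as.integer(2e6 / max(nrow(points), 1)))
  for (s in seq(1L, q, by = chunk)) {
    e <- min(q, s + chunk - 1L)
    qs <- query[s:e, , drop = FALSE]
    d2 <- outer(rowSums(qs^2), rowSums(points^2), `+`) - 2 * qs %*% t(points)
    res[s:e] <- max.col(-d2, ties.method = "first")
  }
  res
}
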