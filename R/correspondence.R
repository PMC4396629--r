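#' Least-squares similarity (Procrustes) fit between labeled point sets
#'
#' Estimates the similarity transform (scale, rotation, translation)
#' minimizing the residual sum of squares mapping the shared fiducials of
#' `src` onto `dst` (Umeyama's closed-form solution; the rotation is proper,
#' determinant +1).
#'
#' @param src,dst [fiducial_set()]s (or matrices with rownames); at least 4
#'   shared names, not all collinear.
#' @return object of class `similarity_transform`: list with `scale`,
#'   `rotation` (3x3), `translation`, `rss` (residual sum of squares) and
#'   `names` (the shared fiducials used).
#' @export
procrustes_fit <- function(src, dst) {
  sp <- if (inherits(src, "fiducial_set")) src$points else as.matrix(src)
  dp <- if (inherits(dst, "fiducial_set")) dst$points else as.matrix(dst)
  shared <- intersect(rownames(sp), rownames(dp))
  if (length(shared) < 4) {
    stop_facesim("need >= 4 shared fiducial names for alignment (got ",
      length(shared), ")",
      class = "facesim_alignment_error"
    )
  }
  x <- sp[shared, , drop = FALSE]
  y <- dp[shared, , drop = FALSE]
  k <- nrow(x)
  mx <- colMeans(x)
  my <- colMeans(y)
  xc <- sweep(x, 2, mx)
  yc <- sweep(y, 2, my)
  sv_x <- svd(xc)$d
  if (sv_x[2] < 1e-8 * max(sv_x[1], 1e-300)) {
    stop_facesim("degenerate (collinear) fiducial configuration",
      class = "facesim_alignment_error"
    )
  }
  sigma_xy <- crossprod(yc, xc) / k # E[(y - my)(x - mx)^T]
  sv <- svd(sigma_xy)
  s_mat <- diag(3)
  if (det(sv$u) * det(sv$v) < 0) s_mat[3, 3] <- -1
  rot <- sv$u %*% s_mat %*% t(sv$v)
  var_x <- sum(xc^2) / k
  scale <- sum(sv$d * diag(s_mat)) / var_x
  trans <- my - scale * as.vector(rot %*% mx)
  fit <- structure(
    list(
      scale = scale, rotation = rot, translation = trans,
      names = shared
    ),
    class = "similarity_transform"
  )
  fit$rss <- sum((apply_transform(fit, x) - y)^2)
  fit
}

#' Apply a similarity transform to points
#'
#' @param trans a `similarity_transform`.
#' @param points `n x 3` matrix.
#' @return transformed `n x 3` matrix.
#' @export
apply_transform <- function(trans, points) {
  sweep(trans$scale * as.matrix(points) %*% t(trans$rotation), 2,
    trans$translation, "+"
  )
}

#' @export
print.similarity_transform <- function(x, ...) {
  cat("<similarity_transform> scale ", signif(x$scale, 6),
    ", RSS ", signif(x$rss, 6), " over ", length(x$names), " fiducials\n",
    sep = ""
  )
  invisible(x)
}

tps_kernel <- function(r) r # biharmonic kernel in 3D, U(r) = r

# all pairwise distances between rows of a (n x 3) and b (k x 3)
cross_dist <- function(a, b) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), `+`) - 2 * a %*% t(b)
  sqrt(pmax(d2, 0))
}

#' Fit an interpolating 3D thin-plate spline
#'
#' Computes the minimum-bending-energy deformation with kernel `U(r) = r`
#' (biharmonic in 3D) that maps each source control point exactly onto its
#' destination partner. The non-affine weights satisfy the TPS side
#' conditions (orthogonality to constants and to the control coordinates).
#' Near-degenerate systems (e.g. nearly coplanar controls) are solved with a
#' small ridge term proportional to the mean kernel magnitude, with a
#' warning.
#'
#' @param src_ctrl,dst_ctrl `k x 3` matrices of control points, equal counts,
#'   `k >= 5`, source points pairwise distinct.
#' @return object of class `tps_deformation`: `src` controls, `affine`
#'   (4 x 3: intercept + linear map), `weights` (k x 3), `kernel`.
#' @export
tps_fit <- function(src_ctrl, dst_ctrl) {
  src <- as_matrix3(src_ctrl, "source controls")
  dst <- as_matrix3(dst_ctrl, "destination controls")
  k <- nrow(src)
  if (nrow(dst) != k || k < 5) {
    stop_facesim("need equal control counts with k >= 5",
      class = "facesim_input_error"
    )
  }
  kmat <- tps_kernel(cross_dist(src, src))
  if (any(kmat[upper.tri(kmat)] == 0)) {
    stop_facesim("duplicate source control points make the TPS system singular",
      class = "facesim_singular_error"
    )
  }
  p <- cbind(1, src)
  m <- rbind(cbind(kmat, p), cbind(t(p), matrix(0, 4, 4)))
  rhs <- rbind(dst, matrix(0, 4, 3))
  sol <- tryCatch(
    {
      if (rcond(m) < 1e-12) stop("ill-conditioned")
      solve(m, rhs)
    },
    error = function(e) {
      ridge <- 1e-8 * mean(kmat)
      warning("near-degenerate TPS system; solving with ridge ", signif(ridge, 3))
      solve(m + diag(ridge, nrow(m)), rhs)
    }
  )
  structure(
    list(
      src = src, weights = sol[seq_len(k), , drop = FALSE],
      affine = sol[k + 1:4, , drop = FALSE], kernel = "U(r)=r"
    ),
    class = "tps_deformation"
  )
}

#' Evaluate a thin-plate-spline deformation
#'
#' @param def a `tps_deformation` from [tps_fit()].
#' @param points `n x 3` matrix of query points.
#' @return deformed `n x 3` matrix.
#' @export
tps_apply <- function(def, points) {
  pts <- as_matrix3(points, "points")
  u <- tps_kernel(cross_dist(pts, def$src))
  cbind(1, pts) %*% def$affine + u %*% def$weights
}

#' @export
print.tps_deformation <- function(x, ...) {
  cat("<tps_deformation> ", nrow(x$src), " controls, kernel ", x$kernel, "\n", sep = "")
  invisible(x)
}

#' Reproduce a target face on the reference topology
#'
#' Runs the dense-correspondence pipeline: (a) Procrustes-fit the reference's
#' modeling fiducials to the target's and transform the reference; (b) map
#' both faces to cylindrical coordinates with the 10-degree forehead tilt
#' (after translating the target's nose tip to (0, 0, 50) mm); (c) warp the
#' reference with a thin-plate spline fitted on the fiducials in cylindrical
#' space; (d) resample the target's radial coordinate and per-channel RGB at
#' the warped reference (phi, z) positions by piecewise-linear interpolation
#' over the target's own projected triangulation; (e) return a mesh on the
#' reference topology, in the target's original frame. Acquisition holes and
#' out-of-hull samples are filled by nearest-neighbor values and flagged.
#'
#' @param ref_mesh,ref_fids the reference head and its fiducials.
#' @param target_mesh,target_fids the target face and its fiducials
#'   (complete modeling set including `nose_tip`).
#' @param tilt_deg forehead tilt in degrees (default 10).
#' @return object of class `reproduced_face`: list with `mesh` (on reference
#'   topology), logical `filled` per vertex, `procrustes` (the similarity
#'   fit), and `coverage` (fraction of vertices interpolated, not filled).
#' @export
reproduce_face <- function(ref_mesh, ref_fids, target_mesh, target_fids,
                           tilt_deg = 10) {
  shared <- intersect(
    fid_names(ref_fids, "modeling"),
    fid_names(target_fids, "modeling")
  )
  pro <- procrustes_fit(
    subset_fiducials(ref_fids, shared),
    subset_fiducials(target_fids, shared)
  )
  ref_v <- apply_transform(pro, ref_mesh$vertices)
  ref_l <- apply_transform(pro, fid_coords(ref_fids, shared))
  # canonical frame: target nose tip at (0, 0, 50) mm
  offset <- c(0, 0, 50) - fid_coords(target_fids, "nose_tip")[1, ]
  tgt_v <- sweep(target_mesh$vertices, 2, offset, "+")
  tgt_l <- sweep(fid_coords(target_fids, shared), 2, offset, "+")
  ref_v <- sweep(ref_v, 2, offset, "+")
  ref_l <- sweep(ref_l, 2, offset, "+")

  cyl_rv <- to_cylindrical(ref_v, tilt_deg)
  cyl_tv <- to_cylindrical(tgt_v, tilt_deg)
  cyl_rl <- to_cylindrical(ref_l, tilt_deg)
  cyl_tl <- to_cylindrical(tgt_l, tilt_deg)

  def <- tps_fit(
    cbind(cyl_rl$rho, cyl_rl$phi, cyl_rl$z),
    cbind(cyl_tl$rho, cyl_tl$phi, cyl_tl$z)
  )
  warped <- tps_apply(def, cbind(cyl_rv$rho, cyl_rv$phi, cyl_rv$z))

  res <- interp_on_triangulation(
    points = cbind(cyl_tv$phi, cyl_tv$z),
    faces = target_mesh$faces,
    values = cbind(cyl_tv$rho, target_mesh$colors),
    query = warped[, 2:3, drop = FALSE],
    nn_scale = c(mean(cyl_tv$rho), 1) # azimuth on an arc-length footing
  )
  rho_new <- res$values[, 1]
  cols_new <- clamp(res$values[, 2:4, drop = FALSE], 0, 1)
  verts <- from_cylindrical(
    list(rho = rho_new, phi = warped[, 2], z = warped[, 3]), tilt_deg
  )
  verts <- sweep(verts, 2, offset, "-")
  structure(
    list(
      mesh = surface_mesh(verts, ref_mesh$faces, cols_new, validate = FALSE),
      filled = res$filled,
      procrustes = pro,
      coverage = mean(!res$filled)
    ),
    class = "reproduced_face"
  )
}

#' @export
print.reproduced_face <- function(x, ...) {
  cat("<reproduced_face> ", nrow(x$mesh$vertices), " vertices, coverage ",
    sprintf("%.1f%%", 100 * x$coverage), ", Procrustes RSS ",
    signif(x$procrustes$rss, 4), "\n",
    sep = ""
  )
  invisible(x)
}

# Closest point on a triangle (Ericson), vectorized over triangles for one
# query point p.
closest_point_triangles <- function(p, a, b, c) {
  ab <- b - a
  ac <- c - a
  ap <- sweep(-a, 2, p, "+")
  d1 <- rowSums(ab * ap)
  d2 <- rowSums(ac * ap)
  bp <- sweep(-b, 2, p, "+")
  d3 <- rowSums(ab * bp)
  d4 <- rowSums(ac * bp)
  cp <- sweep(-c, 2, p, "+")
  d5 <- rowSums(ab * cp)
  d6 <- rowSums(ac * cp)

  va <- d3 * d6 - d5 * d4
  vb <- d5 * d2 - d1 * d6
  vc <- d1 * d4 - d3 * d2
  denom <- va + vb + vc
  v <- vb / denom
  w <- vc / denom
  out <- a + v * ab + w * ac

  vc_edge <- d1 * d4 - d3 * d2
  t_ab <- d1 / (d1 - d3)
  on_ab <- vc_edge <= 0 & d1 >= 0 & d3 <= 0
  out[on_ab, ] <- a[on_ab, , drop = FALSE] + t_ab[on_ab] * ab[on_ab, , drop = FALSE]
  vb_edge <- d5 * d2 - d1 * d6
  t_ac <- d2 / (d2 - d6)
  on_ac <- vb_edge <= 0 & d2 >= 0 & d6 <= 0
  out[on_ac, ] <- a[on_ac, , drop = FALSE] + t_ac[on_ac] * ac[on_ac, , drop = FALSE]
  va_edge <- d3 * d6 - d5 * d4
  t_bc <- (d4 - d3) / ((d4 - d3) + (d5 - d6))
  on_bc <- va_edge <= 0 & (d4 - d3) >= 0 & (d5 - d6) >= 0
  out[on_bc, ] <- b[on_bc, , drop = FALSE] +
    t_bc[on_bc] * (c[on_bc, , drop = FALSE] - b[on_bc, , drop = FALSE])
  out[d1 <= 0 & d2 <= 0, ] <- a[d1 <= 0 & d2 <= 0, , drop = FALSE]
  on_b <- d3 >= 0 & d4 <= d3
  out[on_b, ] <- b[on_b, , drop = FALSE]
  on_c <- d6 >= 0 & d5 <= d6
  out[on_c, ] <- c[on_c, , drop = FALSE]
  out
}

#' Closest points on a mesh surface
#'
#' Exact point-to-triangle projection of each query point onto the surface,
#' with a centroid-radius prefilter to keep the candidate face list small.
#'
#' @param mesh a [surface_mesh()].
#' @param points `q x 3` matrix of query points.
#' @return list with `points` (`q x 3` projected points), `face` (face index
#'   attaining the minimum) and `dist`.
#' @export
closest_point_on_mesh <- function(mesh, points) {
  points <- as_matrix3(points, "query points")
  f <- mesh$faces
  v <- mesh$vertices
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c <- v[f[, 3], , drop = FALSE]
  cent <- (a + b + c) / 3
  rad <- pmax(
    row_norms(a - cent), row_norms(b - cent), row_norms(c - cent)
  )
  q <- nrow(points)
  out <- matrix(0, q, 3)
  face <- integer(q)
  dist <- numeric(q)
  for (i in seq_len(q)) {
    p <- points[i, ]
    dc <- row_norms(sweep(cent, 2, p))
    ub <- min(dc + rad)
    cand <- which(dc - rad <= ub)
    cp <- closest_point_triangles(
      p, a[cand, , drop = FALSE], b[cand, , drop = FALSE], c[cand, , drop = FALSE]
    )
    d <- row_norms(sweep(cp, 2, p))
    j <- which.min(d)
    out[i, ] <- cp[j, ]
    face[i] <- cand[j]
    dist[i] <- d[j]
  }
  list(points = out, face = face, dist = dist)
}

#' Recover fiducials missing on a post-operative face
#'
#' Aligns the pre-operative face to the post-operative one by a Procrustes
#' fit on surgically unaffected fiducials, then allocates each missing
#' fiducial as the closest point on the post-operative surface to the
#' aligned pre-operative fiducial.
#'
#' @param preop_mesh,preop_fids pre-operative face and complete fiducials.
#' @param postop_mesh,postop_fids post-operative face and partial fiducials.
#' @param unaffected names of fiducials unaffected by surgery (present in
#'   both sets, >= 4).
#' @return the completed [fiducial_set()] for the post-operative face.
#' @export
project_missing_fiducials <- function(preop_mesh, preop_fids,
                                      postop_mesh, postop_fids, unaffected) {
  missing <- setdiff(rownames(preop_fids$points), rownames(postop_fids$points))
  if (length(missing) == 0) {
    message("no missing fiducials; returning input unchanged")
    return(postop_fids)
  }
  pro <- procrustes_fit(
    subset_fiducials(preop_fids, unaffected),
    subset_fiducials(postop_fids, unaffected)
  )
  moved <- apply_transform(pro, fid_coords(preop_fids, missing))
  proj <- closest_point_on_mesh(postop_mesh, moved)$points
  rownames(proj) <- missing
  pts <- rbind(postop_fids$points, proj)
  role <- c(postop_fids$role, preop_fids$role[missing])
  fiducial_set(pts, role)
}
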