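# Shared fixtures, all generated in code.

# Small synthetic head; resolution chosen so geometric tests are fast but the
# fiducial snap error stays ~1 mm.
small_head <- function(n = 2000, seed = 1, ...) {
  make_reference_head(head_params(n_vertices = n, seed = seed, ...))
}

# A varied synthetic individual (different global size, feature amplitudes
# and seeded surface wobble).
synth_individual <- function(seed, n = 2000, wobble = 2) {
  p <- with_test_seed(seed, head_params(
    n_vertices = n,
    radius = runif(1, 84, 96),
    nose_amp = runif(1, 16, 24),
    eye_amp = runif(1, 3.5, 6.5),
    mouth_amp = runif(1, 3.5, 6.5),
    wobble_amp = wobble, seed = seed
  ))
  make_reference_head(p)
}

with_test_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

# Planar grid mesh in the z = 50 plane (so its cylindrical projection is
# regular), nx x ny vertices, spacing in mm.
grid_mesh <- function(nx, ny, spacing = 5, z = 50) {
  g <- expand.grid(x = seq_len(nx) - (nx + 1) / 2, y = seq_len(ny) - (ny + 1) / 2)
  v <- cbind(g$x * spacing, g$y * spacing, z)
  i <- rep(seq_len(nx - 1), ny - 1)
  j <- rep(seq_len(ny - 1), each = nx - 1)
  v00 <- i + (j - 1) * nx
  f <- rbind(
    cbind(v00, v00 + 1, v00 + nx + 1),
    cbind(v00, v00 + nx + 1, v00 + nx)
  )
  surface_mesh(v, f)
}

single_triangle <- function() {
  surface_mesh(
    rbind(c(0, 0, 0), c(10, 0, 0), c(0, 10, 0)),
    rbind(c(1, 2, 3)),
    rbind(c(0, 0, 0), c(1, 1, 1), c(0.5, 0.5, 0.5))
  )
}

tetrahedron <- function() {
  surface_mesh(
    rbind(c(0, 0, 0), c(10, 0, 0), c(0, 10, 0), c(0, 0, 10)),
    rbind(c(1, 2, 3), c(1, 2, 4), c(1, 3, 4), c(2, 3, 4))
  )
}

# Random proper rotation matrix.
random_rotation <- function(seed) {
  with_test_seed(seed, {
    q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
    if (det(q) < 0) q[, 1] <- -q[, 1]
    q
  })
}

# Independent slow oracle: minimum distance from point p to any triangle of
# the mesh, via barycentric projection coded separately from the package.
# Faces are prefiltered by a safe centroid-distance bound to keep the dense
# scan tractable.
brute_force_surface_distance <- function(mesh, p) {
  v <- mesh$vertices
  f <- mesh$faces
  cent <- (v[f[, 1], ] + v[f[, 2], ] + v[f[, 3], ]) / 3
  dc <- sqrt(rowSums(sweep(cent, 2, p)^2))
  rad <- sqrt(rowSums((v[f[, 1], ] - cent)^2))
  rad <- pmax(rad, sqrt(rowSums((v[f[, 2], ] - cent)^2)))
  rad <- pmax(rad, sqrt(rowSums((v[f[, 3], ] - cent)^2)))
  keep <- which(dc - rad <= min(dc + rad))
  f <- f[keep, , drop = FALSE]
  best <- Inf
  for (t in seq_len(nrow(f))) {
    a <- v[f[t, 1], ]
    b <- v[f[t, 2], ]
    c <- v[f[t, 3], ]
    # project on plane, clamp barycentrics by dense search over the triangle
    e1 <- b - a
    e2 <- c - a
    m <- cbind(e1, e2)
    uv <- tryCatch(solve(crossprod(m), crossprod(m, p - a)), error = function(e) NULL)
    cand <- list()
    if (!is.null(uv)) cand[[1]] <- c(uv)
    # dense fallback over the simplex covers clamped cases
    gr <- seq(0, 1, length.out = 21)
    for (u in gr) {
      for (w in gr) {
        if (u + w <= 1) cand[[length(cand) + 1]] <- c(u, w)
      }
    }
    for (uw in cand) {
      u <- min(max(uw[1], 0), 1)
      w <- min(max(uw[2], 0), 1)
      if (u + w > 1) {
        s <- u + w
        u <- u / s
        w <- w / s
      }
      q <- a + u * e1 + w * e2
      best <- min(best, sqrt(sum((p - q)^2)))
    }
  }
  best
}
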