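make_fidset <- function(pts) {
  rownames(pts) <- paste0("f", seq_len(nrow(pts)))
  fiducial_set(pts, rep("modeling", nrow(pts)))
}

test_that("Procrustes fit recovers constructed similarity transforms", {
  pts <- with_test_seed(1, matrix(rnorm(30, sd = 20), 10, 3))
  src <- make_fidset(pts)

  ident <- procrustes_fit(src, src)
  expect_equal(ident$scale, 1, tolerance = 1e-12)
  expect_equal(ident$rotation, diag(3), tolerance = 1e-12)
  expect_equal(ident$translation, c(0, 0, 0), tolerance = 1e-10)

  dst <- make_fidset(2 * pts + rep(c(1, 2, 3), each = 10))
  fit <- procrustes_fit(src, dst)
  expect_equal(fit$scale, 2, tolerance = 1e-12)
  expect_equal(fit$rotation, diag(3), tolerance = 1e-12)
  expect_equal(fit$translation, c(1, 2, 3), tolerance = 1e-10)

  rot <- random_rotation(4)
  dst2 <- make_fidset(pts %*% t(rot))
  fit2 <- procrustes_fit(src, dst2)
  expect_lt(max(abs(fit2$rotation - rot)), 1e-8)
  expect_lt(max(abs(apply_transform(fit2, pts) - pts %*% t(rot))), 1e-8)
})

test_that("Procrustes fit agrees with an independent implementation", {
  skip_if_not_installed("vegan")
  pts <- with_test_seed(2, matrix(rnorm(24, sd = 15), 8, 3))
  noisy <- with_test_seed(3, {
    1.7 * pts %*% t(random_rotation(5)) + rep(c(5, -3, 2), each = 8) +
      matrix(rnorm(24, sd = 0.5), 8, 3)
  })
  fit <- procrustes_fit(make_fidset(pts), make_fidset(noisy))
  ref <- vegan::procrustes(noisy, pts, scale = TRUE, symmetric = FALSE)
  expect_lt(max(abs(apply_transform(fit, pts) - stats::fitted(ref))), 1e-8)
})

test_that("degenerate Procrustes configurations are rejected", {
  pts <- with_test_seed(1, matrix(rnorm(30), 10, 3))
  small <- make_fidset(pts[1:3, ])
  expect_error(procrustes_fit(small, small), ">= 4 shared",
    class = "facesim_alignment_error"
  )
  line <- make_fidset(cbind(1:6, 2 * (1:6), -(1:6)))
  expect_error(procrustes_fit(line, line), "collinear",
    class = "facesim_alignment_error"
  )
})

test_that("TPS interpolates controls exactly and reproduces affine maps", {
  src <- with_test_seed(10, matrix(runif(30, -40, 40), 10, 3))
  dst <- with_test_seed(11, src + matrix(rnorm(30, sd = 6), 10, 3))

  ident <- tps_fit(src, src)
  expect_lt(max(abs(ident$weights)), 1e-8)
  expect_equal(ident$affine[2:4, ], diag(3), tolerance = 1e-8)
  expect_lt(max(abs(tps_apply(ident, src) - src)), 1e-8)

  a <- rbind(c(1.2, 0.1, 0), c(-0.2, 0.9, 0.3), c(0, 0.2, 1.1))
  b <- c(4, -2, 7)
  aff_dst <- src %*% t(a) + rep(b, each = nrow(src))
  aff <- tps_fit(src, aff_dst)
  expect_lt(max(abs(aff$weights)), 1e-8)
  # direct affine oracle: evaluation equals the matrix map everywhere
  q <- with_test_seed(12, matrix(runif(60, -60, 60), 20, 3))
  expect_lt(max(abs(tps_apply(aff, q) - (q %*% t(a) + rep(b, each = 20)))), 1e-6)

  fit <- tps_fit(src, dst)
  expect_lt(max(abs(tps_apply(fit, src) - dst)), 1e-8)
  # side conditions: weights orthogonal to constants and coordinates
  expect_lt(max(abs(crossprod(cbind(1, src), fit$weights))), 1e-8)
})

test_that("TPS solution matches an independently coded dense solve", {
  src <- with_test_seed(13, matrix(runif(30, -30, 30), 10, 3))
  dst <- with_test_seed(14, src + matrix(rnorm(30, sd = 4), 10, 3))
  fit <- tps_fit(src, dst)

  # independent dense assembly with explicit loops
  k <- nrow(src)
  m <- matrix(0, k + 4, k + 4)
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      m[i, j] <- sqrt(sum((src[i, ] - src[j, ])^2))
    }
    m[i, k + 1] <- m[k + 1, i] <- 1
    for (d in 1:3) m[i, k + 1 + d] <- m[k + 1 + d, i] <- src[i, d]
  }
  sol <- qr.solve(m, rbind(dst, matrix(0, 4, 3)))
  expect_lt(max(abs(sol[seq_len(k), ] - fit$weights)), 1e-8)
  expect_lt(max(abs(sol[k + 1:4, ] - fit$affine)), 1e-8)

  dup <- src
  dup[2, ] <- dup[1, ]
  expect_error(tps_fit(dup, dst), "duplicate",
    class = "facesim_singular_error"
  )
  coplanar <- cbind(src[, 1:2], 0)
  expect_warning(tps_fit(coplanar, dst), "ridge")
})

test_that("surface interpolation attains the analytic accuracy bound", {
  # analytic radial field rho(phi, z) = 50 + 5 cos(z / 20) on a regular grid
  h_phi <- 0.05
  h_z <- 2.5
  g <- expand.grid(phi = seq(-1, 1, by = h_phi), z = seq(-50, 50, by = h_z))
  nphi <- length(seq(-1, 1, by = h_phi))
  nz <- nrow(g) / nphi
  i <- rep(seq_len(nphi - 1), nz - 1)
  j <- rep(seq_len(nz - 1), each = nphi - 1)
  v00 <- i + (j - 1) * nphi
  faces <- rbind(
    cbind(v00, v00 + 1, v00 + nphi + 1),
    cbind(v00, v00 + nphi + 1, v00 + nphi)
  )
  rho <- 50 + 5 * cos(g$z / 20)
  q <- with_test_seed(20, cbind(runif(500, -0.9, 0.9), runif(500, -45, 45)))
  res <- facesim:::interp_on_triangulation(
    cbind(g$phi, g$z), faces, cbind(rho), q
  )
  expect_false(any(res$filled))
  truth <- 50 + 5 * cos(q[, 2] / 20)
  bound <- max(h_phi, h_z)^2 * (5 / 20^2) / 8 # h^2 max|rho''| / 8
  expect_lt(max(abs(res$values[, 1] - truth)), bound * 1.01)
})

test_that("reproducing the reference itself is the identity pipeline", {
  h <- small_head(n = 2000)
  rep0 <- reproduce_face(h$mesh, h$fids, h$mesh, h$fids)
  expect_lt(max(abs(rep0$mesh$vertices - h$mesh$vertices)), 1e-6)
  expect_lt(max(abs(rep0$mesh$colors - h$mesh$colors)), 1e-6)
  expect_identical(rep0$mesh$faces, h$mesh$faces)
})

test_that("different targets reproduce onto identical topology", {
  h <- small_head(n = 2000)
  t1 <- synth_individual(31)
  t2 <- synth_individual(32)
  r1 <- reproduce_face(h$mesh, h$fids, t1$mesh, t1$fids)
  r2 <- reproduce_face(h$mesh, h$fids, t2$mesh, t2$fids)
  expect_identical(r1$mesh$faces, r2$mesh$faces)
  expect_identical(r1$mesh$faces, h$mesh$faces)
})

test_that("reproduction is equivariant to rigid motion of the target", {
  h <- small_head(n = 2000)
  tgt <- synth_individual(33)
  r0 <- reproduce_face(h$mesh, h$fids, tgt$mesh, tgt$fids)

  rot <- facesim:::rot_x(4) # small rigid motion keeps the face frontal
  t <- c(8, -5, 12)
  moved_mesh <- tgt$mesh
  moved_mesh$vertices <- sweep(tgt$mesh$vertices %*% t(rot), 2, t, "+")
  moved_fids <- tgt$fids
  moved_fids$points <- sweep(tgt$fids$points %*% t(rot), 2, t, "+")
  r1 <- reproduce_face(h$mesh, h$fids, moved_mesh, moved_fids)

  expected <- sweep(r0$mesh$vertices %*% t(rot), 2, t, "+")
  core <- !r0$filled & !r1$filled
  err <- sqrt(rowSums((r1$mesh$vertices - expected)^2))
  expect_lt(stats::quantile(err[core], 0.99), 1)
})

test_that("holes in the target are filled from the hole rim", {
  h <- small_head(n = 2500)
  # deterministic mid-face hole around the left cheek landmark
  ctr <- fid_coords(h$fids, "cheek_center_l")[1, ]
  del <- sqrt(rowSums(sweep(h$mesh$vertices, 2, ctr)^2)) <= 6
  keep <- which(!del)
  remap <- integer(nrow(h$mesh$vertices))
  remap[keep] <- seq_along(keep)
  fk <- h$mesh$faces[!del[h$mesh$faces[, 1]] & !del[h$mesh$faces[, 2]] &
    !del[h$mesh$faces[, 3]], , drop = FALSE]
  fk[] <- remap[fk]
  holed <- surface_mesh(
    h$mesh$vertices[keep, ], fk, h$mesh$colors[keep, ],
    validate = FALSE
  )
  rep1 <- reproduce_face(h$mesh, h$fids, holed, h$fids)
  expect_false(any(!is.finite(rep1$mesh$vertices)))

  over_hole <- which(
    sqrt(rowSums(sweep(h$mesh$vertices, 2, ctr)^2)) < 4 & rep1$filled
  )
  expect_gt(length(over_hole), 0)
  # filled radial values lie within the hole-rim radial range
  rim <- which(abs(sqrt(rowSums(sweep(holed$vertices, 2, ctr)^2)) - 8) < 3)
  rim_rho <- range(to_cylindrical(holed$vertices[rim, , drop = FALSE])$rho)
  fill_rho <- to_cylindrical(rep1$mesh$vertices[over_hole, , drop = FALSE])$rho
  expect_true(all(fill_rho >= rim_rho[1] - 0.5 & fill_rho <= rim_rho[2] + 0.5))
})

test_that("missing fiducials are recovered by projection onto the surface", {
  h <- small_head(n = 2000)
  pre_fids <- h$fids
  drop <- c("cheek_center_l", "zygion_l")
  keep <- setdiff(rownames(pre_fids$points), drop)
  post_fids <- subset_fiducials(pre_fids, keep)
  unaff <- c("nose_tip", "nasion", "menton", "exocanthion_r", "gonion_r", "trichion")

  # identical pre/post: recovered points equal the originals
  rec <- project_missing_fiducials(h$mesh, pre_fids, h$mesh, post_fids, unaff)
  expect_lt(
    max(abs(fid_coords(rec, drop) - fid_coords(pre_fids, drop))), 1e-6
  )

  # rigidly moved post-op face: recovery follows the motion
  rot <- random_rotation(6)
  t <- c(3, 4, -6)
  moved_mesh <- h$mesh
  moved_mesh$vertices <- sweep(h$mesh$vertices %*% t(rot), 2, t, "+")
  moved_fids <- post_fids
  moved_fids$points <- sweep(post_fids$points %*% t(rot), 2, t, "+")
  rec2 <- project_missing_fiducials(h$mesh, pre_fids, moved_mesh, moved_fids, unaff)
  expected <- sweep(fid_coords(pre_fids, drop) %*% t(rot), 2, t, "+")
  expect_lt(max(abs(fid_coords(rec2, drop) - expected)), 1e-6)

  expect_message(
    project_missing_fiducials(h$mesh, pre_fids, h$mesh, pre_fids, unaff),
    "no missing"
  )
})

test_that("recovered fiducials land on a deformed post-operative surface", {
  h <- small_head(n = 2000)
  vid <- attr(h$fids, "vertex_id")["cheek_center_l"]
  ctr <- h$mesh$vertices[vid, ]
  # crater: push the surface inward under one fiducial
  post <- h$mesh
  d <- sqrt(rowSums(sweep(post$vertices, 2, ctr)^2))
  nrm <- facesim:::vertex_normals(h$mesh)
  push <- ifelse(d < 20, 8 * exp(-0.5 * (d / 8)^2), 0)
  post$vertices <- post$vertices - nrm * push
  post_fids <- subset_fiducials(
    h$fids, setdiff(rownames(h$fids$points), "cheek_center_l")
  )
  unaff <- c("nose_tip", "nasion", "menton", "exocanthion_r", "gonion_r", "trichion")
  rec <- project_missing_fiducials(h$mesh, h$fids, post, post_fids, unaff)
  p <- fid_coords(rec, "cheek_center_l")[1, ]
  # closest-point oracle: brute force over the faces (the oracle's dense
  # barycentric scan itself resolves edges to ~0.1 mm)
  expect_lt(brute_force_surface_distance(post, p), 0.1)
})
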