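# Shared stitching fixture: model fitted on a synthetic series, target = a
# different synthetic individual reproduced on the reference topology.
stitch_fixture <- function(n = 2500) {
  h <- small_head(n = n)
  scen <- disfigurement_scenario(sigma = 0, gain = rep(1, 4), offset = rep(0, 4))
  visits <- lapply(make_longitudinal_series(h, scen), `[[`, "mesh")
  fit <- fit_eigendisfigurement(visits, scen$roi, h)
  tgt <- synth_individual(77, n = n)
  trep <- reproduce_face(h$mesh, h$fids, tgt$mesh, tgt$fids)
  list(head = h, model = fit$model, target = trep$mesh)
}

test_that("the graph Laplacian has the hand-computed structure", {
  tri <- single_triangle()
  g <- build_laplacian(tri)
  expect_equal(g$degree, c(2, 2, 2))
  l <- as.matrix(g$L)
  expect_equal(diag(l), c(2, 2, 2), ignore_attr = TRUE)
  expect_equal(rowSums(l), c(0, 0, 0), ignore_attr = TRUE)

  # two triangles sharing an edge
  quad <- surface_mesh(
    rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0)),
    rbind(c(1, 2, 3), c(1, 3, 4))
  )
  l2 <- as.matrix(build_laplacian(quad)$L)
  expect_equal(
    l2,
    rbind(
      c(3, -1, -1, -1), c(-1, 2, -1, 0),
      c(-1, -1, 3, -1), c(-1, 0, -1, 2)
    ),
    ignore_attr = TRUE
  )
})

test_that("the Laplacian equals D - A from an independent edge scan", {
  h <- small_head(n = 1500)
  g <- build_laplacian(h$mesh)
  n <- nrow(h$mesh$vertices)

  # brute-force oracle: adjacency accumulated face by face
  a <- matrix(0, n, n)
  for (t in seq_len(nrow(h$mesh$faces))) {
    f <- h$mesh$faces[t, ]
    a[f[1], f[2]] <- a[f[2], f[1]] <- 1
    a[f[2], f[3]] <- a[f[3], f[2]] <- 1
    a[f[1], f[3]] <- a[f[3], f[1]] <- 1
  }
  l_oracle <- diag(rowSums(a)) - a
  l <- as.matrix(g$L)
  expect_equal(l, l_oracle, ignore_attr = TRUE)

  # invariants: symmetry, zero row sums, positive semidefinite quadratic form
  expect_equal(l, t(l))
  expect_lt(max(abs(rowSums(l))), 1e-12)
  xs <- with_test_seed(29, matrix(rnorm(n * 20), n, 20))
  expect_gt(min(colSums(xs * (l %*% xs))), -1e-8)
})

test_that("system assembly matches a hand-assembled dense system on a fan", {
  # 20-vertex fan: hub vertex 1 joined to a rim path 2..20
  n <- 20
  rim <- 2:n
  ang <- seq(0, pi, length.out = n - 1)
  v <- rbind(c(0, 0, 0), cbind(cos(ang), sin(ang), 0))
  f <- cbind(1, rim[-length(rim)], rim[-1])
  fan <- surface_mesh(v, f)
  g <- build_laplacian(fan)

  interior <- 1L
  boundary <- as.integer(rim)
  ids <- sort(c(interior, boundary))
  guide <- as.numeric(v[ids, 1])^2
  target <- as.numeric(v[, 2])
  sys <- assemble_system(g, interior, boundary, guide, target)

  # dense oracle assembled with explicit loops
  l_dense <- as.matrix(g$L)
  a_oracle <- matrix(0, n, n)
  b_oracle <- numeric(n)
  a_oracle[1, 1] <- l_dense[1, 1]
  b_oracle[1] <- sum(l_dense[1, ids] * guide) - sum(l_dense[1, boundary] * target[boundary])
  for (r in 2:n) {
    a_oracle[r, r] <- 1
    b_oracle[r] <- target[boundary[r - 1]]
  }
  expect_equal(as.matrix(sys$A), a_oracle[c(interior, boundary), c(interior, boundary)],
    ignore_attr = TRUE
  )
  expect_equal(sys$b, b_oracle, ignore_attr = TRUE)
})

test_that("constant guidance leaves only boundary terms in the right side", {
  h <- small_head(n = 1500)
  sel <- roi_vertex_set(h$mesh, h$fids, h$regions, "M")
  g <- build_laplacian(h$mesh)
  ids <- sort(c(sel$interior, sel$boundary))
  sys <- assemble_system(
    g, sel$interior, sel$boundary,
    guide = rep(4.2, length(ids)), # L of a constant vanishes
    target_values = rep(0, g$n)
  )
  expect_lt(max(abs(sys$b[seq_along(sel$interior)])), 1e-12)

  # an interior vertex with an unlisted neighbor is a construction error
  expect_error(
    assemble_system(g, ids, integer(0), rep(0, length(ids)), rep(0, g$n)),
    "boundary is incomplete",
    class = "facesim_problem_error"
  )
})

test_that("the biconjugate-gradient solver meets its contracts", {
  # identity system solves in one iteration
  one <- solve_poisson(Matrix::Diagonal(5), c(1, -2, 3, 0.5, 9))
  expect_lte(one$iterations, 1L)
  expect_equal(one$x, c(1, -2, 3, 0.5, 9))

  # dense-solver oracle on a small SPD system
  m <- with_test_seed(30, {
    r <- matrix(rnorm(400), 20, 20)
    crossprod(r) + diag(20)
  })
  b <- with_test_seed(31, rnorm(20))
  sol <- solve_poisson(methods::as(m, "CsparseMatrix"), b, tol = 1e-12, max_iter = 500)
  expect_lt(max(abs(sol$x - solve(m, b))), 1e-6)

  # a singular Laplacian with an incompatible right side is an error
  tri_l <- build_laplacian(single_triangle())$L
  expect_error(
    suppressMessages(solve_poisson(tri_l, c(1, 0, 0), max_iter = 5)),
    "singular",
    class = "facesim_solver_error"
  )
})

test_that("iterative and dense direct solutions agree on small meshes", {
  gm <- grid_mesh(14, 14, spacing = 5) # 196 vertices
  pts <- rbind(
    a = c(-26, -26, 50), b = c(26, -26, 50), c = c(26, 26, 50), d = c(-26, 26, 50)
  )
  fids <- fiducial_set(pts, rep("modeling", 4))
  regions <- region_definition(list(SQ = c("a", "b", "c", "d")))
  sel <- roi_vertex_set(gm, fids, regions, "SQ", tilt_deg = 0)
  g <- build_laplacian(gm)
  ids <- sort(c(sel$interior, sel$boundary))
  guide <- with_test_seed(32, rnorm(length(ids), sd = 3))
  target <- gm$vertices[, 1] * 0.3
  sys <- assemble_system(g, sel$interior, sel$boundary, guide, target)
  sol <- solve_poisson(sys$A, sys$b, tol = 1e-10)
  dense <- solve(as.matrix(sys$A), sys$b)
  expect_lt(max(abs(sol$x - dense)), 1e-6)
  expect_true(sol$converged)
})

test_that("harmonic infill obeys the discrete maximum principle", {
  h <- small_head(n = 2000)
  sel <- roi_vertex_set(h$mesh, h$fids, h$regions, c("RC"))
  g <- build_laplacian(h$mesh)
  ids <- sort(c(sel$interior, sel$boundary))
  target <- h$mesh$vertices[, 3]
  sys <- assemble_system(
    g, sel$interior, sel$boundary,
    guide = rep(0, length(ids)), target_values = target
  )
  sol <- solve_poisson(sys$A, sys$b, tol = 1e-10)
  interior_vals <- sol$x[seq_along(sel$interior)]
  rng <- range(target[sel$boundary])
  expect_true(all(interior_vals >= rng[1] - 1e-8))
  expect_true(all(interior_vals <= rng[2] + 1e-8))
})

test_that("stitching is linear in the guidance field", {
  gm <- grid_mesh(12, 12, spacing = 5)
  pts <- rbind(
    a = c(-21, -21, 50), b = c(21, -21, 50), c = c(21, 21, 50), d = c(-21, 21, 50)
  )
  fids <- fiducial_set(pts, rep("modeling", 4))
  regions <- region_definition(list(SQ = c("a", "b", "c", "d")))
  sel <- roi_vertex_set(gm, fids, regions, "SQ", tilt_deg = 0)
  g <- build_laplacian(gm)
  ids <- sort(c(sel$interior, sel$boundary))
  target <- gm$vertices[, 2] * 0.1
  g1 <- with_test_seed(33, rnorm(length(ids)))
  g2 <- with_test_seed(34, rnorm(length(ids)))

  solve_for <- function(guide) {
    sys <- assemble_system(g, sel$interior, sel$boundary, guide, target)
    solve_poisson(sys$A, sys$b, tol = 1e-12)$x
  }
  x_h <- solve_for(rep(0, length(ids)))
  x1 <- solve_for(g1)
  x2 <- solve_for(g2)
  x12 <- solve_for(g1 + g2)
  expect_lt(max(abs((x12 - x_h) - ((x1 - x_h) + (x2 - x_h)))), 1e-8)
})

test_that("identity cloning returns the target itself", {
  fx <- stitch_fixture(n = 2000)
  # a model whose synthesis at lambda 0 equals the target's own ROI values
  m <- fx$model
  dof <- facesim:::roi_dof(m$vertex_ids)
  tv <- flatten_face(fx$target)
  m$mean_s <- tv$s[dof]
  m$mean_t <- tv$t[dof]
  out <- stitch_disfigurement(fx$target, m, 0, tol = 1e-10)
  expect_lt(max(abs(out$vertices - fx$target$vertices)), 1e-6)
  expect_lt(max(abs(out$colors - fx$target$colors)), 1e-6)
})

test_that("stitching alters only the ROI interior and satisfies the system", {
  fx <- stitch_fixture(n = 2000)
  out <- stitch_disfigurement(fx$target, fx$model, 0.5, tol = 1e-10)
  outside <- setdiff(seq_len(nrow(out$vertices)), fx$model$interior)
  expect_identical(out$vertices[outside, ], fx$target$vertices[outside, ])
  expect_identical(out$colors[outside, ], fx$target$colors[outside, ])

  # interior rows satisfy L f = L s_hat to solver accuracy
  g <- build_laplacian(fx$target)
  sy <- synthesize_disfigurement(fx$model, 0.5)
  s_mat <- matrix(sy$s_hat, ncol = 3, byrow = TRUE)
  guide_full <- numeric(g$n)
  guide_full[fx$model$vertex_ids] <- s_mat[, 1]
  lf <- as.numeric(g$L %*% out$vertices[, 1])
  ls <- as.numeric(g$L %*% guide_full)
  expect_lt(max(abs(lf[fx$model$interior] - ls[fx$model$interior])), 1e-6)

  d <- attr(out, "stitch_diagnostics")
  expect_equal(nrow(d), 6)
  expect_true(all(d$iterations <= 1000))
  expect_false(any(d$fallback))
})

test_that("severity survives the stitch within a tenth", {
  # the severity sweep renders varying lambda on the patient's own face, so
  # recovery is measured by stitching onto the pre-operative reproduced face
  h <- small_head(n = 2500)
  scen <- disfigurement_scenario(seed = 3)
  visits <- make_longitudinal_series(h, scen)
  reps <- lapply(visits, function(v) {
    r <- reproduce_face(h$mesh, h$fids, v$mesh, v$fids)
    r$mesh <- normalize_mesh_colors(r$mesh)
    r
  })
  fit <- fit_eigendisfigurement(reps, scen$roi, h)
  out <- stitch_disfigurement(reps[[1]]$mesh, fit$model, 0.5, tol = 1e-10)
  expect_gte(project_lambda(fit$model, out), 0.4)
  expect_lte(project_lambda(fit$model, out), 0.6)
  expect_gte(project_lambda(fit$model, out, "textural"), 0.4)
  expect_lte(project_lambda(fit$model, out, "textural"), 0.6)
})
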