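#' Graph Laplacian of a triangle mesh
#'
#' Uniform (0/1) adjacency weights from the triangulation's edge set: the
#' weight matrix `W` is symmetric with zero diagonal, the connectivity
#' vector `tau` counts edges per vertex, and the Laplacian is
#' `L = diag(tau) - W` (symmetric positive semidefinite, zero row sums).
#'
#' @param mesh a [surface_mesh()].
#' @return object of class `mesh_graph`: list with sparse `L`, `degree`,
#'   `edges`, and `n`.
#' @export
build_laplacian <- function(mesh) {
  n <- nrow(mesh$vertices)
  edges <- mesh_edges(mesh)
  deg <- tabulate(edges, nbins = n)
  if (any(deg == 0)) {
    warning(sum(deg == 0), " isolated vertex/vertices: zero Laplacian row(s)")
  }
  i <- c(edges[, 1], edges[, 2], seq_len(n))
  j <- c(edges[, 2], edges[, 1], seq_len(n))
  x <- c(rep(-1, 2 * nrow(edges)), deg)
  l <- Matrix::sparseMatrix(i = i, j = j, x = x, dims = c(n, n))
  structure(list(L = l, degree = deg, edges = edges, n = n),
    class = "mesh_graph"
  )
}

#' @export
print.mesh_graph <- function(x, ...) {
  cat("<mesh_graph> ", x$n, " vertices, ", nrow(x$edges), " edges\n", sep = "")
  invisible(x)
}

#' Assemble the Dirichlet Poisson system for one component
#'
#' Builds the sparse linear system whose solution is the stitched value of
#' one component (x, y, z, r, g or b) over the ROI: interior rows equate the
#' graph Laplacian of the unknown to the Laplacian of the guidance values
#' (the divergence of the guidance gradient field), with boundary-unknown
#' contributions moved to the right-hand side; boundary rows are identity
#' rows pinning the target's own values (Dirichlet condition).
#'
#' @param graph a `mesh_graph` of the target mesh.
#' @param interior,boundary ROI vertex id vectors (from [roi_vertex_set()]
#'   or a fitted model).
#' @param guide numeric guidance values on the ROI vertices, aligned with
#'   `sort(c(interior, boundary))`.
#' @param target_values numeric vector of the component over all mesh
#'   vertices (supplies the Dirichlet values).
#' @return list with sparse `A`, right-hand side `b`, and `ids` (the unknown
#'   vertex ids, `c(interior, boundary)` order).
#' @export
assemble_system <- function(graph, interior, boundary, guide, target_values) {
  ids <- sort(c(interior, boundary))
  if (length(guide) != length(ids)) {
    stop_facesim("guidance values must align with the ROI vertex set",
      class = "facesim_input_error"
    )
  }
  in_roi <- logical(graph$n)
  in_roi[ids] <- TRUE
  e <- graph$edges
  out_nb <- c(
    e[in_roi[e[, 1]] & !in_roi[e[, 2]], 1],
    c(e[!in_roi[e[, 1]] & in_roi[e[, 2]], 2])
  )
  if (any(out_nb %in% interior)) {
    stop_facesim(
      "interior vertex has a neighbor outside the ROI: boundary is incomplete",
      class = "facesim_problem_error"
    )
  }
  guide_full <- numeric(graph$n)
  guide_full[ids] <- guide

  l_ii <- graph$L[interior, interior, drop = FALSE]
  l_ib <- graph$L[interior, boundary, drop = FALSE]
  l_iroi <- graph$L[interior, ids, drop = FALSE]
  b_int <- as.numeric(l_iroi %*% guide_full[ids]) -
    as.numeric(l_ib %*% target_values[boundary])

  n_i <- length(interior)
  n_b <- length(boundary)
  a <- Matrix::bdiag(l_ii, Matrix::Diagonal(n_b))
  b <- c(b_int, target_values[boundary])
  list(A = methods::as(a, "CsparseMatrix"), b = b, ids = c(interior, boundary))
}

#' Biconjugate-gradient solution of a sparse system
#'
#' Unpreconditioned biconjugate gradient iteration from a zero initial
#' guess, stopping when the relative residual `||b - Ax|| / ||b||` drops
#' below `tol`. If the iteration does not converge within `max_iter`, the
#' system is solved by a direct sparse factorization and the event logged.
#'
#' @param a square sparse (or dense) matrix.
#' @param b right-hand side vector.
#' @param tol relative residual tolerance (default 1e-8).
#' @param max_iter iteration cap (default 1000).
#' @return list with `x`, `iterations`, `residual` (relative), `converged`,
#'   `fallback` (`TRUE` if the direct solve was used).
#' @export
solve_poisson <- function(a, b, tol = 1e-8, max_iter = 1000) {
  nb <- sqrt(sum(b^2))
  if (nb == 0) {
    return(list(
      x = numeric(length(b)), iterations = 0L, residual = 0,
      converged = TRUE, fallback = FALSE
    ))
  }
  x <- numeric(length(b))
  r <- b
  rt <- r
  p <- numeric(length(b))
  pt <- numeric(length(b))
  rho_prev <- 1
  at <- Matrix::t(a)
  converged <- FALSE
  iter <- 0L
  rel <- 1
  while (iter < max_iter) {
    rho <- sum(rt * r)
    if (rho == 0) break # breakdown
    if (iter == 0L) {
      p <- r
      pt <- rt
    } else {
      beta <- rho / rho_prev
      p <- r + beta * p
      pt <- rt + beta * pt
    }
    q <- as.numeric(a %*% p)
    qt <- as.numeric(at %*% pt)
    denom <- sum(pt * q)
    if (denom == 0) break
    alpha <- rho / denom
    x <- x + alpha * p
    r <- r - alpha * q
    rt <- rt - alpha * qt
    rho_prev <- rho
    iter <- iter + 1L
    rel <- sqrt(sum(r^2)) / nb
    if (rel <= tol) {
      converged <- TRUE
      break
    }
  }
  fallback <- FALSE
  if (!converged) {
    sing <- tryCatch(
      {
        x <- as.numeric(Matrix::solve(a, b))
        rel <- sqrt(sum((b - as.numeric(a %*% x))^2)) / nb
        fallback <- TRUE
        message(
          "biconjugate gradient did not converge in ", max_iter,
          " iterations; used direct sparse factorization"
        )
        FALSE
      },
      error = function(e) TRUE
    )
    if (sing) {
      stop_facesim("singular stitching system (no boundary rows?)",
        class = "facesim_solver_error"
      )
    }
  }
  list(
    x = x, iterations = iter, residual = rel,
    converged = converged || fallback, fallback = fallback
  )
}

#' Stitch a learned disfigurement onto a target face
#'
#' Synthesizes the disfigurement at severity `lambda` and blends it
#' seamlessly into the target by solving six discrete Poisson problems (x,
#' y, z coordinates and r, g, b channels) on the mesh graph, using the
#' Laplacian of the synthesized values as guidance and the target's own
#' values as Dirichlet boundary conditions. Vertices outside the ROI are
#' returned bit-identical to the input; colors are clipped to `[0, 1]` after
#' the solve.
#'
#' @param target_mesh a [surface_mesh()] on the reference topology (e.g. a
#'   reproduced face).
#' @param model a fitted `eigen_disfigurement`.
#' @param lambda severity.
#' @param tol,max_iter solver controls (see [solve_poisson()]).
#' @return the simulated [surface_mesh()], with a `stitch_diagnostics`
#'   attribute (per-component iterations and residuals).
#' @export
stitch_disfigurement <- function(target_mesh, model, lambda,
                                 tol = 1e-8, max_iter = 1000) {
  if (nrow(target_mesh$vertices) != model$n_ref) {
    stop_facesim("target must share the model's reference topology",
      class = "facesim_input_error"
    )
  }
  synth <- synthesize_disfigurement(model, lambda)
  graph <- build_laplacian(target_mesh)
  interior <- model$interior
  boundary <- model$boundary

  s_mat <- matrix(synth$s_hat, ncol = 3, byrow = TRUE) # ROI vertices x 3
  t_mat <- matrix(synth$t_hat, ncol = 3, byrow = TRUE)

  out <- target_mesh
  diag_rows <- list()
  comps <- c("x", "y", "z", "r", "g", "b")
  for (ci in seq_along(comps)) {
    if (ci <= 3) {
      guide <- s_mat[, ci]
      tv <- target_mesh$vertices[, ci]
    } else {
      guide <- t_mat[, ci - 3]
      tv <- target_mesh$colors[, ci - 3]
    }
    sys <- assemble_system(graph, interior, boundary, guide, tv)
    sol <- solve_poisson(sys$A, sys$b, tol = tol, max_iter = max_iter)
    vals <- sol$x[seq_along(interior)]
    if (ci <= 3) {
      out$vertices[interior, ci] <- vals
    } else {
      out$colors[interior, ci - 3] <- clamp(vals, 0, 1)
    }
    diag_rows[[ci]] <- tibble::tibble(
      component = comps[ci], iterations = sol$iterations,
      residual = sol$residual, fallback = sol$fallback
    )
  }
  attr(out, "stitch_diagnostics") <- do.call(rbind, diag_rows)
  out
}
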