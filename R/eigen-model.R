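#' Flatten a face into structural and textural vectors
#'
#' Interleaves per-vertex coordinates and colors into the canonical face
#' vectors: structural `s = (x1, y1, z1, ..., xn, yn, zn)` and textural
#' `t = (r1, g1, b1, ..., rn, gn, bn)`, both in `R^(3n)`.
#'
#' @param face a [surface_mesh()] or `reproduced_face`.
#' @return object of class `face_vectors`: list with `s`, `t`, `n`.
#' @export
flatten_face <- function(face) {
  mesh <- if (inherits(face, "reproduced_face")) face$mesh else face
  structure(
    list(
      s = as.vector(t(mesh$vertices)),
      t = as.vector(t(mesh$colors)),
      n = nrow(mesh$vertices)
    ),
    class = "face_vectors"
  )
}

#' Rebuild a mesh from face vectors
#'
#' Inverse of [flatten_face()] given the face connectivity.
#'
#' @param vec a `face_vectors` object.
#' @param faces `m x 3` face index matrix.
#' @return a [surface_mesh()].
#' @export
unflatten_face <- function(vec, faces) {
  surface_mesh(
    matrix(vec$s, ncol = 3, byrow = TRUE),
    faces,
    clamp(matrix(vec$t, ncol = 3, byrow = TRUE), 0, 1),
    validate = FALSE
  )
}

# Structural/textural DOF indices of a vertex id set (interleaved layout).
roi_dof <- function(vertex_ids) {
  as.vector(t(outer(3 * (as.integer(vertex_ids) - 1L), 1:3, `+`)))
}

# Snapshot PCA of column snapshots X (d x N): mean, centered snapshots,
# Gram eigendecomposition lifted to unit-norm components, scores.
snapshot_pca <- function(x) {
  n <- ncol(x)
  mu <- rowMeans(x)
  phi <- x - mu
  gram <- crossprod(phi) / n
  eg <- eigen(gram, symmetric = TRUE)
  vals <- pmax(eg$values, 0)
  tol <- max(vals) * 1e-12
  keep <- which(vals > tol)
  if (length(keep) == 0) {
    stop_facesim("all snapshots identical: degenerate model",
      class = "facesim_degenerate_error"
    )
  }
  comps <- phi %*% eg$vectors[, keep, drop = FALSE]
  norms <- sqrt(colSums(comps^2))
  comps <- sweep(comps, 2, norms, "/")
  scores <- crossprod(phi, comps) # N x K, projections of snapshots
  # deterministic sign: the snapshot with the largest |score| (ties -> the
  # latest visit) scores positive
  for (k in seq_along(keep)) {
    sc <- scores[, k]
    jmax <- max(which(abs(sc) == max(abs(sc))))
    if (sc[jmax] < 0) {
      comps[, k] <- -comps[, k]
      scores[, k] <- -sc
    }
  }
  list(
    mean = mu, phi = phi, gram = gram,
    eigenvalues = vals, small_vectors = eg$vectors,
    components = comps, scores = scores,
    var_frac = vals / sum(vals)
  )
}

#' Learn an eigen-disfigurement from a longitudinal series
#'
#' Restricts the structural and textural face vectors of a patient's visits
#' to the disfigurement ROI, and captures the dominant longitudinal change
#' with snapshot PCA: the small Gram matrix of the centered visit vectors is
#' eigendecomposed and its eigenvectors lifted to full-length unit
#' eigenvectors (feasible even though the ambient covariance is huge). The
#' first structural and textural components are the eigen-disfigurement; the
#' severity axis is scaled so that `lambda = +/-1` spans the observed
#' extremes (`lambda`-scale = largest absolute visit score).
#'
#' @param visits list of faces on the reference topology
#'   ([surface_mesh()] or `reproduced_face`, ideally color-normalized), the
#'   visits `j = 0..p` with `p >= 2`.
#' @param roi character vector of ROI names.
#' @param reference list with `mesh`, `fids`, `regions` of the reference
#'   head (defines the ROI vertex set on the shared topology).
#' @param id identifier of the disfigurement.
#' @param tilt_deg tilt for the ROI projection.
#' @return list with `model` (class `eigen_disfigurement`) and `workspace`
#'   (class `pca_workspace`, holding all components and scores for both the
#'   structural and textural decompositions).
#' @export
fit_eigendisfigurement <- function(visits, roi, reference, id = "d1",
                                   tilt_deg = 10) {
  if (length(visits) < 3) {
    stop_facesim("need >= 3 visits (p >= 2)", class = "facesim_input_error")
  }
  sel <- roi_vertex_set(
    reference$mesh, reference$fids, reference$regions, roi, tilt_deg
  )
  ids <- sort(c(sel$interior, sel$boundary))
  dof <- roi_dof(ids)
  n_ref <- nrow(reference$mesh$vertices)

  vecs <- lapply(visits, flatten_face)
  bad <- vapply(vecs, function(v) v$n != n_ref, logical(1))
  if (any(bad)) {
    stop_facesim("all visits must share the reference topology",
      class = "facesim_input_error"
    )
  }
  s_mat <- vapply(vecs, function(v) v$s[dof], numeric(length(dof)))
  t_mat <- vapply(vecs, function(v) v$t[dof], numeric(length(dof)))

  pca_s <- snapshot_pca(s_mat)
  pca_t <- snapshot_pca(t_mat)

  model <- structure(
    list(
      id = id, roi = roi,
      vertex_ids = ids, interior = sel$interior, boundary = sel$boundary,
      n_ref = n_ref,
      mean_s = pca_s$mean, mean_t = pca_t$mean,
      u1 = pca_s$components[, 1], v1 = pca_t$components[, 1],
      lambda_scale_s = max(abs(pca_s$scores[, 1])),
      lambda_scale_t = max(abs(pca_t$scores[, 1])),
      var_frac_s = pca_s$var_frac, var_frac_t = pca_t$var_frac
    ),
    class = "eigen_disfigurement"
  )
  workspace <- structure(
    list(structural = pca_s, textural = pca_t),
    class = "pca_workspace"
  )
  list(model = model, workspace = workspace)
}

#' @export
print.eigen_disfigurement <- function(x, ...) {
  cat("<eigen_disfigurement> '", x$id, "' on ROI {",
    paste(x$roi, collapse = ","), "}: ", length(x$vertex_ids),
    " vertices; first-component variance ",
    sprintf("%.0f%% (structural), %.0f%% (textural)\n",
      100 * x$var_frac_s[1], 100 * x$var_frac_t[1]),
    sep = ""
  )
  invisible(x)
}

#' Synthesize a disfigurement at severity lambda
#'
#' Evaluates the learned model on its ROI: `s_hat = S_bar + lambda * c_s *
#' u1` and `t_hat = T_bar + lambda * c_t * v1`, where the scales `c` make
#' `lambda` dimensionless (`lambda = 0` is the mean appearance, `+/-1` the
#' observed extremes). Values `|lambda| > 1` exaggerate the disfigurement
#' and are permitted with a warning.
#'
#' @param model an `eigen_disfigurement`.
#' @param lambda severity scalar.
#' @return object of class `synthesized_disfigurement`: `s_hat`, `t_hat`
#'   (over the ROI DOFs), `lambda`, `vertex_ids`, `id`.
#' @export
synthesize_disfigurement <- function(model, lambda) {
  if (abs(lambda) > 1) {
    warning("severity |lambda| > 1 exaggerates beyond the observed range")
  }
  structure(
    list(
      s_hat = model$mean_s + lambda * model$lambda_scale_s * model$u1,
      t_hat = model$mean_t + lambda * model$lambda_scale_t * model$v1,
      lambda = lambda, vertex_ids = model$vertex_ids, id = model$id
    ),
    class = "synthesized_disfigurement"
  )
}

#' Recover the severity of a face under a fitted model
#'
#' Projects the ROI-restricted face vector onto the first eigen-
#' disfigurement: `lambda_hat = <face_roi - mean, u1> / lambda_scale`.
#'
#' @param model an `eigen_disfigurement`.
#' @param face a [surface_mesh()], `reproduced_face`, or `face_vectors`.
#' @param which `"structural"` or `"textural"`.
#' @return the estimated severity (scalar).
#' @export
project_lambda <- function(model, face, which = c("structural", "textural")) {
  which <- match.arg(which)
  vec <- if (inherits(face, "face_vectors")) face else flatten_face(face)
  dof <- roi_dof(model$vertex_ids)
  if (which == "structural") {
    sum((vec$s[dof] - model$mean_s) * model$u1) / model$lambda_scale_s
  } else {
    sum((vec$t[dof] - model$mean_t) * model$v1) / model$lambda_scale_t
  }
}

#' Serialize / load an eigen-disfigurement model
#'
#' Plain-JSON archive holding the means, first eigenvectors, severity
#' scales, ROI recipe and provenance.
#'
#' @param model an `eigen_disfigurement`.
#' @param path output path (conventionally `*.edm.json`).
#' @return [read_eigendisfigurement()] returns the model.
#' @export
write_eigendisfigurement <- function(model, path) {
  obj <- unclass(model)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_eigendisfigurement
#' @export
read_eigendisfigurement <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$vertex_ids <- as.integer(obj$vertex_ids)
  obj$interior <- as.integer(obj$interior)
  obj$boundary <- as.integer(obj$boundary)
  obj$n_ref <- as.integer(obj$n_ref)
  structure(obj, class = "eigen_disfigurement")
}
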