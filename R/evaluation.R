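#' Derive peripheral validation fiducials
#'
#' Peripheral face areas have few visible landmarks, so validation points
#' there are constructed: for each pair of modeling fiducials, the Euclidean
#' midpoint is projected to the closest point on the surface and returned as
#' a validation-role fiducial.
#'
#' @param mesh a [surface_mesh()].
#' @param fids a [fiducial_set()] containing the pair members.
#' @param pairs named list of 2-element character vectors (default: the 3
#'   peripheral pairs `p1`..`p3` on forehead, cheek and neck).
#' @return a [fiducial_set()] of validation points (one per pair).
#' @export
derive_peripheral_validation_points <- function(mesh, fids,
                                                pairs = list(
                                                  p1 = c("trichion", "eyebrow_lateral_r"),
                                                  p2 = c("zygion_l", "gonion_l"),
                                                  p3 = c("gonion_r", "neck_upper_r")
                                                )) {
  mids <- t(vapply(pairs, function(pr) {
    colMeans(fid_coords(fids, pr))
  }, numeric(3)))
  proj <- closest_point_on_mesh(mesh, mids)$points
  rownames(proj) <- names(pairs)
  fiducial_set(proj, rep("validation", nrow(proj)))
}

#' Validation-fiducial reproduction error
#'
#' For each validation fiducial, computes the mean and standard deviation
#' (over a set of faces) of the Euclidean distance between the original
#' face's validation point and the corresponding point of its reproduction
#' on the reference topology. The correspondence point on a reproduced face
#' is the vertex onto which the reference's validation fiducial snaps.
#'
#' @param targets list of faces, each a list with `mesh` and `fids` (with
#'   validation-role fiducials).
#' @param reproduced list of `reproduced_face` objects paired with
#'   `targets`.
#' @param reference list with `mesh` and `fids` of the reference head.
#' @param points validation fiducial names to evaluate (default: all
#'   validation names shared by the reference and every target).
#' @return a tibble with columns `point`, `mean_mm`, `sd_mm`.
#' @export
validation_error <- function(targets, reproduced, reference, points = NULL) {
  if (length(targets) != length(reproduced)) {
    stop_facesim("targets and reproduced lists must be paired",
      class = "facesim_input_error"
    )
  }
  ref_val <- fid_names(reference$fids, "validation")
  if (is.null(points)) {
    points <- ref_val
    for (tg in targets) points <- intersect(points, fid_names(tg$fids, "validation"))
  }
  if (length(points) == 0) {
    stop_facesim("no shared validation fiducials", class = "facesim_input_error")
  }
  vid <- attr(reference$fids, "vertex_id")
  if (is.null(vid)) {
    vid <- nearest_point_index(reference$mesh$vertices, fid_coords(reference$fids))
    names(vid) <- rownames(reference$fids$points)
  }
  err <- matrix(NA_real_, length(targets), length(points),
    dimnames = list(NULL, points)
  )
  for (i in seq_along(targets)) {
    rep_v <- reproduced[[i]]$mesh$vertices[vid[points], , drop = FALSE]
    orig <- fid_coords(targets[[i]]$fids, points)
    err[i, ] <- row_norms(rep_v - orig)
  }
  tibble::tibble(
    point = points,
    mean_mm = unname(colMeans(err)),
    sd_mm = unname(apply(err, 2, stats::sd))
  )
}

#' Fiducial-perturbation sensitivity study
#'
#' Emulates landmark annotation error: each repeat displaces every modeling
#' fiducial of the target by exactly the given magnitude in a uniformly
#' random 3D direction, re-runs the reproduction pipeline, and records the
#' validation errors; results are averaged over repeats. Derived peripheral
#' validation points are excluded since the scrambling would move their
#' defining landmarks.
#'
#' @param reference list with `mesh`, `fids` (reference head).
#' @param target list with `mesh`, `fids` (target face).
#' @param magnitudes perturbation magnitudes in mm (default
#'   `c(1.5, 2, 2.5, 3)`; magnitude 0, the unperturbed baseline, is always
#'   included).
#' @param repeats repeats per magnitude (default 10).
#' @param seed integer seed.
#' @param exclude_validation validation names to exclude (default the
#'   peripheral `p1`..`p3`).
#' @param tilt_deg tilt for the reproduction pipeline.
#' @return a tibble with columns `point`, `magnitude_mm`, `mean_mm` (mean
#'   over repeats of the validation error).
#' @export
perturbation_study <- function(reference, target,
                               magnitudes = c(1.5, 2, 2.5, 3),
                               repeats = 10, seed = 1,
                               exclude_validation = c("p1", "p2", "p3"),
                               tilt_deg = 10) {
  if (any(magnitudes < 0) || repeats < 1) {
    stop_facesim("magnitudes must be >= 0 and repeats >= 1",
      class = "facesim_parameter_error"
    )
  }
  points <- setdiff(
    intersect(
      fid_names(reference$fids, "validation"),
      fid_names(target$fids, "validation")
    ),
    exclude_validation
  )
  mod_names <- fid_names(target$fids, "modeling")
  base_rep <- reproduce_face(
    reference$mesh, reference$fids, target$mesh, target$fids, tilt_deg
  )
  base_err <- validation_error(
    list(target), list(base_rep), reference, points
  )
  rows <- list(tibble::tibble(
    point = base_err$point, magnitude_mm = 0, mean_mm = base_err$mean_mm
  ))
  magnitudes <- magnitudes[magnitudes > 0]
  with_seed(seed, {
    for (mag in magnitudes) {
      acc <- matrix(0, repeats, length(points))
      for (r in seq_len(repeats)) {
        dir <- matrix(rnorm(3 * length(mod_names)), ncol = 3)
        dir <- dir / row_norms(dir)
        pf <- target$fids
        pf$points[mod_names, ] <- pf$points[mod_names, ] + mag * dir
        rep_r <- reproduce_face(
          reference$mesh, reference$fids, target$mesh, pf, tilt_deg
        )
        acc[r, ] <- validation_error(
          list(target), list(rep_r), reference, points
        )$mean_mm
      }
      rows[[length(rows) + 1]] <- tibble::tibble(
        point = points, magnitude_mm = mag, mean_mm = colMeans(acc)
      )
    }
  })
  do.call(rbind, rows)
}

#' Rating summary statistics
#'
#' `median_rating()` is the sample median (even counts: mean of the two
#' middle order statistics); `mad_rating()` is the median of absolute
#' deviations from the median, without a consistency constant.
#'
#' @param values numeric ratings on the 1-9 scale.
#' @return a scalar.
#' @export
median_rating <- function(values) {
  if (length(values) == 0) {
    stop_facesim("empty rating list", class = "facesim_input_error")
  }
  median(values)
}

#' @rdname median_rating
#' @export
mad_rating <- function(values) {
  if (length(values) == 0) {
    stop_facesim("empty rating list", class = "facesim_input_error")
  }
  median(abs(values - median(values)))
}

#' Group median of per-case rating medians
#'
#' Filters the rating table by simulation type, target gender and/or
#' disfigurement location, and returns the median of the selected rows'
#' per-case medians (the operationalization that reproduces the published
#' group summaries).
#'
#' @param table a rating tibble as returned by [observer_ratings()].
#' @param type,gender,location optional filters (`NULL` = no filter).
#' @return a scalar group median.
#' @export
group_median <- function(table, type = NULL, gender = NULL, location = NULL) {
  sel <- rep(TRUE, nrow(table))
  if (!is.null(type)) sel <- sel & table$type %in% type
  if (!is.null(gender)) sel <- sel & table$gender %in% gender
  if (!is.null(location)) sel <- sel & table$location %in% location
  if (!any(sel)) {
    stop_facesim("rating filter selects no rows", class = "facesim_filter_error")
  }
  median_rating(table$median[sel])
}
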