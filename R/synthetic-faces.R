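#' Parameters for the synthetic reference head
#'
#' The synthetic head stands in for the reference ("mannequin") model and for
#' individual study faces: a smooth, ear-free, closed-front facial shell with
#' parametric nose/eye/mouth features, generated on a regular grid in the
#' (azimuth, height) plane. Varying `radius`, the feature amplitudes and the
#' seeded low-frequency `wobble` produces distinct individuals.
#'
#' @param n_vertices approximate vertex budget (>= 500).
#' @param radius global head radius in mm.
#' @param nose_amp,eye_amp,mouth_amp feature bump amplitudes in mm (the eye
#'   amplitude is an indentation).
#' @param wobble_amp amplitude (mm) of seeded smooth random surface
#'   modulation emulating inter-individual shape variation (0 = none).
#' @param seed integer seed; the generator is a pure function of its seed and
#'   parameters.
#' @return list of class `head_params`.
#' @export
head_params <- function(n_vertices = 20000, radius = 90, nose_amp = 20,
                        eye_amp = 5, mouth_amp = 5, wobble_amp = 0, seed = 1) {
  if (n_vertices < 500) {
    stop_facesim("vertex budget must be >= 500", class = "facesim_parameter_error")
  }
  if (radius <= 0) {
    stop_facesim("radius must be positive", class = "facesim_parameter_error")
  }
  structure(
    list(
      n_vertices = as.integer(n_vertices), radius = radius,
      nose_amp = nose_amp, eye_amp = eye_amp, mouth_amp = mouth_amp,
      wobble_amp = wobble_amp, seed = as.integer(seed)
    ),
    class = "head_params"
  )
}

# Fiducial schema of the synthetic head: 61 modeling points (45 anthropometric
# + 16 outline) and 7 mid-face validation points, in (phi [rad], y [mm])
# parameter coordinates. Landmark names follow facial anthropometry where a
# standard name exists. phi > 0 is the subject's left.
synthetic_fiducial_schema <- function() {
  mid <- function(name, y) data.frame(name = name, phi = 0, y = y)
  pair <- function(name, phi, y) {
    data.frame(name = paste0(name, c("_l", "_r")), phi = c(phi, -phi), y = y)
  }
  modeling <- rbind(
    mid("trichion", 82), mid("metopion", 60), mid("nasion", 30),
    mid("rhinion", 12), mid("nose_tip", 0), mid("subnasale", -12),
    mid("labiale_superius", -26), mid("stomion", -32),
    mid("labiale_inferius", -38), mid("sublabiale", -46),
    mid("pogonion", -56), mid("menton", -66), mid("neck_center", -90),
    pair("eyebrow_medial", 0.28, 45), pair("eyebrow_lateral", 0.58, 45),
    pair("endocanthion", 0.30, 28), pair("exocanthion", 0.55, 28),
    pair("palpebrale_superius", 0.42, 33), pair("palpebrale_inferius", 0.42, 23),
    pair("orbitale", 0.42, 16), pair("alare", 0.15, -8),
    pair("alar_crest", 0.20, -13), pair("cheilion", 0.28, -32),
    pair("zygion", 0.72, 8), pair("cheek_center", 0.55, -10),
    pair("gonion", 0.75, -45), pair("jawline", 0.45, -58),
    pair("neck_upper", 0.55, -78), pair("neck_lower", 0.40, -100),
    mid("outline_t", 88),
    pair("outline_1", 0.60, 84), pair("outline_2", 1.15, 70),
    pair("outline_3", 1.20, 40), pair("outline_4", 1.20, 5),
    pair("outline_5", 1.20, -35), pair("outline_6", 1.15, -70),
    pair("outline_7", 0.60, -100),
    mid("outline_b", -105)
  )
  modeling$role <- "modeling"
  validation <- rbind(
    mid("g", 40), mid("nb1", 22), mid("nb2", 6),
    data.frame(name = c("sbal1", "sbal2"), phi = c(0.13, -0.13), y = -14),
    data.frame(name = c("l1", "l2"), phi = c(0.14, -0.14), y = -26)
  )
  validation$role <- "validation"
  rbind(modeling, validation)
}

# Default 9-ROI polygon table over the synthetic fiducial schema. Polygons
# are closed loops in the (phi, z) plane; the chin is absorbed into the
# mouth ROI.
synthetic_region_definition <- function() {
  region_definition(list(
    FH = c(
      "outline_2_l", "outline_1_l", "outline_t", "outline_1_r", "outline_2_r",
      "eyebrow_lateral_r", "eyebrow_medial_r", "eyebrow_medial_l",
      "eyebrow_lateral_l"
    ),
    LE = c(
      "eyebrow_medial_l", "eyebrow_lateral_l", "exocanthion_l",
      "orbitale_l", "endocanthion_l"
    ),
    RE = c(
      "eyebrow_medial_r", "eyebrow_lateral_r", "exocanthion_r",
      "orbitale_r", "endocanthion_r"
    ),
    N = c(
      "nasion", "endocanthion_l", "alar_crest_l", "subnasale",
      "alar_crest_r", "endocanthion_r"
    ),
    LC = c(
      "exocanthion_l", "zygion_l", "gonion_l", "jawline_l",
      "cheilion_l", "alar_crest_l", "orbitale_l"
    ),
    RC = c(
      "exocanthion_r", "zygion_r", "gonion_r", "jawline_r",
      "cheilion_r", "alar_crest_r", "orbitale_r"
    ),
    M = c(
      "subnasale", "alar_crest_l", "cheilion_l", "jawline_l",
      "menton", "jawline_r", "cheilion_r", "alar_crest_r"
    ),
    LN = c(
      "menton", "jawline_l", "gonion_l", "outline_6_l",
      "outline_7_l", "outline_b"
    ),
    RN = c(
      "menton", "jawline_r", "gonion_r", "outline_6_r",
      "outline_7_r", "outline_b"
    )
  ))
}

# Radial surface function of the synthetic head, rho(phi, y), in mm. The
# vertical taper is kept mild and the face leans slightly forward with
# height (see make_reference_head) so that after the 10-degree tilt the
# cylinder axis through the aligned nose stays well inside the surface at
# every height: the (phi, z) projection must remain single-valued.
synthetic_head_rho <- function(phi, y, params, wobble_coef = NULL) {
  r <- params$radius
  g <- 1 - 0.08 * ((y + 10) / 120)^2
  rho <- r * (0.80 + 0.20 * cos(1.1 * phi)) * g
  bump <- function(c_phi, c_y, s_phi, s_y, amp) {
    amp * exp(-0.5 * ((phi - c_phi) / s_phi)^2 - 0.5 * ((y - c_y) / s_y)^2)
  }
  rho <- rho +
    bump(0, 0, 0.13, 11, params$nose_amp) +
    bump(0, 14, 0.08, 16, 0.35 * params$nose_amp) +
    bump(0.42, 28, 0.12, 8, -params$eye_amp) +
    bump(-0.42, 28, 0.12, 8, -params$eye_amp) +
    bump(0.42, 44, 0.14, 6, 4) + bump(-0.42, 44, 0.14, 6, 4) +
    bump(0, -32, 0.28, 6, params$mouth_amp) +
    bump(0, -55, 0.20, 10, 8) +
    bump(0.55, 5, 0.20, 14, 6) + bump(-0.55, 5, 0.20, 14, 6)
  if (!is.null(wobble_coef)) {
    w <- 0
    for (k in seq_len(nrow(wobble_coef))) {
      w <- w + wobble_coef[k, 1] *
        cos(wobble_coef[k, 2] * phi + wobble_coef[k, 3]) *
        cos(wobble_coef[k, 4] * (y / 60) + wobble_coef[k, 5])
    }
    rho <- rho + params$wobble_amp * w
  }
  rho
}

# Base skin colors of the synthetic head at (phi, y), plus seeded smooth
# mottling.
synthetic_head_colors <- function(phi, y, mottle = NULL) {
  base <- cbind(
    0.84 + 0.02 * cos(phi), 0.64 + 0.02 * cos(phi), 0.54 + 0.015 * cos(phi)
  )
  lip <- exp(-0.5 * ((phi / 0.24)^2 + ((y + 32) / 5)^2))
  brow <- exp(-0.5 * (((abs(phi) - 0.43) / 0.13)^2 + ((y - 44) / 3.2)^2))
  base[, 1] <- base[, 1] + 0.05 * lip - 0.30 * brow
  base[, 2] <- base[, 2] - 0.20 * lip - 0.28 * brow
  base[, 3] <- base[, 3] - 0.18 * lip - 0.25 * brow
  if (!is.null(mottle)) base <- base + mottle
  clamp(base, 0, 1)
}

#' Generate the synthetic reference head
#'
#' Builds a seeded, deterministic head-like facial shell (grid-triangulated
#' in the azimuth/height plane) together with its complete 61-point modeling
#' fiducial set, 7 mid-face validation fiducials (all snapped to mesh
#' vertices), and the default 9-ROI region definition. The nose tip is
#' aligned to (0, 0, 50) mm.
#'
#' @param params a [head_params()].
#' @return list with elements `mesh` ([surface_mesh()]), `fids`
#'   ([fiducial_set()]) and `regions` ([region_definition()]).
#' @export
make_reference_head <- function(params = head_params()) {
  stopifnot(inherits(params, "head_params"))
  phi_max <- 1.25
  y_rng <- c(-110, 85)
  lean <- 0.15 # forward lean of the face plane with height (mm per mm)
  aspect <- (2 * phi_max * params$radius) / diff(y_rng) # ~ metric aspect
  ny <- max(10L, as.integer(round(sqrt(params$n_vertices / aspect))))
  nphi <- max(10L, as.integer(round(params$n_vertices / ny)))
  phi_g <- seq(-phi_max, phi_max, length.out = nphi)
  y_g <- seq(y_rng[1], y_rng[2], length.out = ny)
  grid <- expand.grid(phi = phi_g, y = y_g)

  wob <- NULL
  mottle <- NULL
  with_seed(params$seed, {
    if (params$wobble_amp != 0) {
      wob <- cbind(
        rnorm(6, 0, 0.5), runif(6, 0.5, 2.5), runif(6, 0, 2 * pi),
        runif(6, 0.5, 2.5), runif(6, 0, 2 * pi)
      )
    }
    amp <- matrix(rnorm(18, 0, 0.01), 6, 3)
    frq <- matrix(runif(12, 0.3, 3), 6, 2)
    phs <- matrix(runif(12, 0, 2 * pi), 6, 2)
    mottle <- matrix(0, nrow(grid), 3)
    for (k in 1:6) {
      m <- cos(frq[k, 1] * grid$phi + phs[k, 1]) *
        cos(frq[k, 2] * grid$y / 50 + phs[k, 2])
      mottle <- mottle + outer(m, amp[k, ])
    }
  })

  rho <- synthetic_head_rho(grid$phi, grid$y, params, wob)
  verts <- cbind(rho * sin(grid$phi), grid$y, rho * cos(grid$phi) + lean * grid$y)
  cols <- synthetic_head_colors(grid$phi, grid$y, mottle)

  # grid triangulation: vertex (i, j) -> index i + (j-1)*nphi
  i <- rep(seq_len(nphi - 1L), ny - 1L)
  j <- rep(seq_len(ny - 1L), each = nphi - 1L)
  v00 <- i + (j - 1L) * nphi
  v10 <- v00 + 1L
  v01 <- v00 + nphi
  v11 <- v01 + 1L
  faces <- rbind(cbind(v00, v10, v11), cbind(v00, v11, v01))

  mesh <- surface_mesh(verts, faces, cols)

  schema <- synthetic_fiducial_schema()
  gx <- clamp(round((schema$phi + phi_max) / (2 * phi_max) * (nphi - 1L)) + 1L, 1, nphi)
  gy <- clamp(round((schema$y - y_rng[1]) / diff(y_rng) * (ny - 1L)) + 1L, 1, ny)
  vid <- as.integer(gx + (gy - 1L) * nphi)
  if (anyDuplicated(vid)) {
    stop_facesim(
      "vertex budget too small to place all fiducials on distinct vertices",
      class = "facesim_parameter_error"
    )
  }
  pts <- mesh$vertices[vid, , drop = FALSE]
  rownames(pts) <- schema$name
  fids <- fiducial_set(pts, schema$role)
  attr(fids, "vertex_id") <- stats::setNames(vid, schema$name)

  aligned <- align_nose_tip(mesh, fids)
  list(mesh = aligned$mesh, fids = aligned$fids, regions = synthetic_region_definition())
}

#' Longitudinal disfigurement scenario
#'
#' Describes the synthetic emulation of a patient's reconstruction course:
#' a localized structural bump (flap-like swelling, Gaussian falloff along
#' vertex normals) whose amplitude follows a per-visit schedule, a texture
#' discoloration patch over the same support, i.i.d. sensor noise, and
#' global per-visit brightness gain/offset (the acquisition drift that color
#' normalization must undo). Visit 0 is pre-operative.
#'
#' @param roi character vector of ROI names the disfigurement occupies.
#' @param center fiducial name at the bump center.
#' @param radius bump support radius (mm); displacement is zero outside. The
#'   default 20 mm (a 4 cm flap) keeps the support inside the default
#'   cheek+neck ROI, consistent with the premise that the disfigurement is
#'   local to its ROI.
#' @param bump_schedule numeric vector, bump amplitude (mm) per visit
#'   `j = 0..p` (p >= 2).
#' @param color_shift `(p+1) x 3` matrix of per-visit RGB shifts at the patch
#'   center.
#' @param sigma sensor noise standard deviation (mm).
#' @param gain,offset per-visit global brightness gain and offset.
#' @param holes list with `count` and `radius` (mm) for acquisition holes
#'   (0 = none).
#' @param seed integer seed.
#' @return list of class `disfigurement_scenario`.
#' @export
disfigurement_scenario <- function(roi = c("LC", "LN"),
                                   center = "cheek_center_l",
                                   radius = 20,
                                   bump_schedule = c(0, 6, 9, 12),
                                   color_shift = outer(
                                     c(0, 0.6, 0.85, 1),
                                     c(0.08, -0.07, -0.09)
                                   ),
                                   sigma = 0.15,
                                   gain = c(1, 1.06, 0.95, 1.03),
                                   offset = c(0, 0.02, -0.02, 0.01),
                                   holes = list(count = 0, radius = 4),
                                   seed = 1) {
  p1 <- length(bump_schedule)
  color_shift <- as.matrix(color_shift)
  if (p1 < 3) {
    stop_facesim("need at least 3 visits (p >= 2)", class = "facesim_parameter_error")
  }
  if (nrow(color_shift) != p1 || length(gain) != p1 || length(offset) != p1) {
    stop_facesim(
      "per-visit schedules must share length p + 1 = ", p1,
      class = "facesim_parameter_error"
    )
  }
  if (radius <= 0 || !all(is.finite(bump_schedule))) {
    stop_facesim("bump radius must be > 0 and amplitudes finite",
      class = "facesim_parameter_error"
    )
  }
  structure(
    list(
      roi = roi, center = center, radius = radius,
      bump_schedule = bump_schedule, color_shift = color_shift,
      sigma = sigma, gain = gain, offset = offset, holes = holes,
      seed = as.integer(seed)
    ),
    class = "disfigurement_scenario"
  )
}

#' Generate a longitudinal patient-like series
#'
#' Applies the scenario to the base face at each visit `j = 0..p`: structural
#' bump displacement along vertex normals with Gaussian falloff (truncated at
#' the support radius), texture patch shift, i.i.d. vertex noise
#' `N(0, sigma^2)` per coordinate, and global brightness gain/offset.
#' Fiducials inside the bump are displaced with the surface.
#'
#' @param base list with `mesh` and `fids` (e.g. from
#'   [make_reference_head()]).
#' @param scenario a [disfigurement_scenario()].
#' @return list of visits, each a list with `mesh` and `fids`.
#' @export
make_longitudinal_series <- function(base, scenario) {
  stopifnot(inherits(scenario, "disfigurement_scenario"))
  mesh <- base$mesh
  fids <- base$fids
  center <- fid_coords(fids, scenario$center)[1, ]
  normals <- vertex_normals(mesh)
  d_v <- row_norms(sweep(mesh$vertices, 2, center))
  d_f <- row_norms(sweep(fids$points, 2, center))
  s_b <- scenario$radius / 2.5
  fall_v <- ifelse(d_v < scenario$radius, exp(-0.5 * (d_v / s_b)^2), 0)
  fall_f <- ifelse(d_f < scenario$radius, exp(-0.5 * (d_f / s_b)^2), 0)
  # fiducial normals: nearest vertex normal
  nn_f <- nearest_point_index(mesh$vertices, fids$points)

  p1 <- length(scenario$bump_schedule)
  visits <- vector("list", p1)
  with_seed(scenario$seed, {
    for (j in seq_len(p1)) {
      amp <- scenario$bump_schedule[j]
      v <- mesh$vertices + normals * (amp * fall_v)
      if (scenario$sigma > 0) {
        v <- v + matrix(rnorm(length(v), 0, scenario$sigma), nrow(v), 3)
      }
      shift <- scenario$color_shift[j, ]
      cols <- mesh$colors + outer(fall_v, shift)
      cols <- clamp(scenario$gain[j] * cols + scenario$offset[j], 0, 1)
      f <- fids
      f$points <- fids$points + normals[nn_f, , drop = FALSE] * (amp * fall_f)
      vm <- surface_mesh(v, mesh$faces, cols, validate = FALSE)
      if (scenario$holes$count > 0) {
        vm <- inject_holes(vm, scenario$holes$count, scenario$holes$radius,
          seed = scenario$seed + 7L * j
        )
      }
      visits[[j]] <- list(mesh = vm, fids = f)
    }
  })
  visits
}

#' Delete acquisition holes from a mesh
#'
#' Samples `count` hole centers among the mesh vertices (seeded) and deletes
#' all vertices within `radius` mm of each center, together with their
#' incident faces, emulating speckle-pattern dropouts of stereo acquisition.
#'
#' @param mesh a [surface_mesh()].
#' @param count number of holes.
#' @param radius hole radius in mm.
#' @param seed integer seed.
#' @param fids optional [fiducial_set()]; a warning is logged if a hole
#'   swallows the neighborhood of a fiducial.
#' @return the mesh with holes (a valid [surface_mesh()]).
#' @export
inject_holes <- function(mesh, count, radius, seed = 1, fids = NULL) {
  if (count == 0) {
    return(mesh)
  }
  ext <- max(apply(mesh$vertices, 2, function(x) diff(range(x))))
  if (radius >= ext) {
    stop_facesim("hole radius must be smaller than the mesh extent",
      class = "facesim_parameter_error"
    )
  }
  n <- nrow(mesh$vertices)
  del <- rep(FALSE, n)
  centers <- NULL
  with_seed(seed, {
    centers <- mesh$vertices[sample.int(n, count), , drop = FALSE]
    for (k in seq_len(count)) {
      del <- del | row_norms(sweep(mesh$vertices, 2, centers[k, ])) <= radius
    }
  })
  if (!is.null(fids)) {
    nn <- nearest_point_index(mesh$vertices, fids$points)
    gone <- del[nn]
    if (any(gone)) {
      warning(
        "hole(s) removed the surface under fiducial(s): ",
        paste(rownames(fids$points)[gone], collapse = ", ")
      )
    }
  }
  keep <- which(!del)
  remap <- integer(n)
  remap[keep] <- seq_along(keep)
  f <- mesh$faces
  fk <- !del[f[, 1]] & !del[f[, 2]] & !del[f[, 3]]
  f <- f[fk, , drop = FALSE]
  f[] <- remap[f]
  out <- surface_mesh(mesh$vertices[keep, , drop = FALSE], f,
    mesh$colors[keep, , drop = FALSE],
    validate = FALSE
  )
  attr(out, "hole_centers") <- centers
  out
}

#' Packaged observer plausibility ratings
#'
#' Per-case summary statistics (median, MAD, min, max on a 9-point Likert
#' scale) of 4 medical professionals' plausibility ratings of 32 stimuli:
#' 26 simulated disfigurements (severity 0.5), 2 real patient faces, and 4
#' exaggerated simulations (severity 1.3).
#'
#' @return a tibble with columns `type` (`simulated`, `real`, `exaggerated`),
#'   `location` (`mid-face`/`peripheral`), `gender` of the target face
#'   (`female`/`male`/`n/a`), `source`, `median`, `mad`, `min`, `max`.
#' @export
observer_ratings <- function() {
  path <- system.file("extdata", "observer_ratings.csv", package = "facesim")
  df <- read.csv(path, stringsAsFactors = FALSE)
  stopifnot(
    all(df$min <= df$median), all(df$median <= df$max),
    all(df$min >= 1), all(df$max <= 9), all(df$mad >= 0)
  )
  tibble::as_tibble(df)
}
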