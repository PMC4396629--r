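#' Per-channel contrast stretching
#'
#' Normalizes longitudinal brightness and color-temperature drift by
#' stretching each color channel independently so that a fixed fraction of
#' the data saturates at each tail: values below the lower
#' `saturation`-quantile (or above the upper one) are clipped, and the
#' clipped range is affinely rescaled to `range`. A constant channel is
#' returned unchanged. The map is invariant to positive affine transforms of
#' the input channel, which is exactly what removes per-visit gain/offset
#' drift.
#'
#' @param colors `n x 3` RGB matrix in `[0, 1]` (or any numeric matrix;
#'   channels are columns).
#' @param saturation fraction of the data saturated per tail (default 0.01,
#'   i.e. one percent); must lie in `[0, 0.5)`.
#' @param range output range, default `c(0, 1)`.
#' @return matrix of the same shape, channels stretched into `range`.
#' @export
contrast_stretch <- function(colors, saturation = 0.01, range = c(0, 1)) {
  if (saturation < 0 || saturation >= 0.5) {
    stop_facesim("saturation fraction must lie in [0, 0.5)",
      class = "facesim_parameter_error"
    )
  }
  colors <- as.matrix(colors)
  out <- colors
  for (ch in seq_len(ncol(colors))) {
    x <- colors[, ch]
    lo <- as.numeric(quantile(x, saturation, type = 7, names = FALSE))
    hi <- as.numeric(quantile(x, 1 - saturation, type = 7, names = FALSE))
    if (hi <= lo) next # constant (degenerate) channel: leave unchanged
    y <- (clamp(x, lo, hi) - lo) / (hi - lo)
    out[, ch] <- range[1] + y * (range[2] - range[1])
  }
  out
}

#' Contrast-stretch a mesh's colors
#'
#' Applies [contrast_stretch()] to all vertex colors of one face (whole-image
#' usage, not per ROI).
#'
#' @param mesh a [surface_mesh()].
#' @inheritParams contrast_stretch
#' @return the mesh with normalized colors.
#' @export
normalize_mesh_colors <- function(mesh, saturation = 0.01) {
  mesh$colors <- contrast_stretch(mesh$colors, saturation)
  mesh
}
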