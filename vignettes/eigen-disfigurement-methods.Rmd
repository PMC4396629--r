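---
title: "Modeling and simulating facial disfigurement on 3D meshes: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling and simulating facial disfigurement on 3D meshes: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(facesim)
```

# The problem

Reconstructive surgery for facial cancer leaves many patients with lasting,
localized changes of facial shape and skin appearance. Studying how such
disfigurement is perceived requires stimuli in which its *type, location
and severity* can be varied at will — something photographs of real
patients cannot offer. `facesim` builds such stimuli: it learns one
patient's disfigurement from longitudinal colored 3D scans and stitches it,
at a chosen severity, onto another face.

A face is a colored triangle mesh `F` with a structural component
`s ∈ R^(3n)` (interleaved vertex coordinates, mm) and a textural component
`t ∈ R^(3n)` (interleaved RGB, floats in [0, 1]). All faces are expressed
on one fixed topology so that vectors from different faces and visits are
comparable entry by entry.

# Dense correspondence

The reference head is warped to each target face in five steps: nose-tip
alignment to (0, 0, 50) mm; a landmark Procrustes similarity fit of the
reference to the target; mapping of both to cylindrical coordinates
`(ρ, φ, z)` (azimuth zero toward the face, branch cut at the back of the
head) after rotating the forehead back by `tilt_deg`; an exact thin-plate
spline on the shared modeling landmarks, applied to the reference in
cylindrical space; and resampling of the target's `ρ` and RGB at the warped
reference `(φ, z)` positions.

Assumptions worth stating explicitly:

* **Single-valued radial graph.** The cropped face must be star-shaped
  about the vertical axis through the aligned nose: every ray from the axis
  meets the surface once. This holds for cropped faces (ears removed); it
  fails for full heads, which is one reason the crop matters.
* **Similarity, not general affine.** The landmark pre-alignment is an
  ordinary Procrustes similarity (scale, rotation, translation) — the
  closed-form least-squares fit with a proper rotation. A general affine
  fit would let shear leak subject identity into the warp.
* **TPS in cylindrical space.** The spline (kernel `U(r) = r`, exact
  interpolation, side conditions enforced through the bordered system) is
  fitted and applied in `(ρ, φ, z)` treated as a 3-space, because the
  surrounding steps already operate there. Fitting in Cartesian space is
  defensible; we chose consistency with the resampling domain. The face
  occupies an azimuth interval well away from the branch cut, so the φ
  seam never intersects the data.
* **The target's own triangulation is the interpolant.** Resampling uses
  piecewise-linear interpolation over the target mesh projected to
  `(φ, z)`, rather than a Delaunay triangulation of scattered points: the
  mesh connectivity *is* the surface, and where the projection folds
  (residual lateral geometry) the triangle with the largest interpolated ρ
  — the outermost sheet — wins. Queries covered by no triangle (scan
  holes, trimmed borders) take the nearest vertex's values, with the
  azimuth scaled by the mean radius so "nearest" is measured in arc
  length; these vertices are flagged (`filled`) so downstream code can
  treat them as imputed.

Post-operative faces may lack landmarks destroyed by surgery;
`project_missing_fiducials()` aligns the pre-operative face on unaffected
landmarks and projects the missing ones to the closest point of the
post-operative surface (exact point-triangle projection).

## Color normalization

Per-channel contrast stretching clips each channel at its lower and upper
`saturation` quantiles (default 0.01 per tail, linear-interpolated
empirical quantiles) and rescales affinely to [0, 1]; constant channels
pass through. The map is invariant to positive affine intensity changes,
which is precisely the per-visit gain/offset drift it is meant to remove.
It is applied to all vertices of one face at once, never per ROI. We read
the one-percent convention as *per tail*; the total clipped mass is
therefore about 2%.

# The eigen-disfigurement

For one patient with visits `j = 0..p` (pre-operative visit 0 included),
the ROI-restricted structural vectors are averaged (`S̄`, the sample mean
over all `p + 1` visits — we read the source's missing divisor and its
`j = 1..p` summation bounds as notational slips; using every snapshot in
both mean and covariance is the standard snapshot-PCA construction) and
centered. The eigenvectors of the huge covariance are obtained from the
small `(p+1) × (p+1)` Gram matrix and lifted; the textural decomposition is
computed identically. Only the first component `u₁` (and `v₁`) is used: the
reconstruction course dominates within-patient variation, so on both the
synthetic conditions and the motivating clinical data the first component
carries at least half the variance.

Three conventions make the model reproducible:

* **ROI restriction first.** PCA runs on ROI-restricted vectors (the
  component is defined only on `φᵢ`), not on whole-face vectors masked
  afterwards.
* **Severity scale.** Eigenvectors are unit length, and λ is made
  dimensionless by `c = max_j |⟨Φ_j, u₁⟩|`, so λ = ±1 spans the observed
  extremes, λ = 0 is the mean appearance, and λ = 1.3 is a deliberate
  exaggeration (allowed, with a warning). The absolute physical scale of
  the severity axis is this package's definition; the source never fixes
  one.
* **Sign.** The visit with the largest absolute score (ties: the latest
  visit) scores positive. Refitting gives bit-identical components.
* **One λ for shape and texture.** Surgery changes both together, so a
  single severity multiplies both components; their scales `c_s, c_t` are
  estimated separately.

`project_lambda()` inverts the synthesis on the component:
`λ̂ = ⟨face_ROI − S̄, u₁⟩ / c`.

# Stitching

The synthesized `ŝ, t̂` are blended into the target by guided
interpolation: minimize `∬ |∇f − ∇ŝ|²` over the ROI subject to `f = f*`
(the target's own values) on the ROI boundary. Discretely, the mesh graph
Laplacian `L = Γ − W` with uniform 0/1 adjacency weights (deliberately not
cotangent weights — fidelity to the formulation wins over graphics
convention) gives one sparse linear system per component: interior rows
`L f = L ŝ` (the divergence of the guidance field reduces to `L ŝ`, so no
explicit per-face gradient operator is needed), boundary rows pinned to the
target. The boundary `∂φᵢ` consists of ROI vertices with a neighbor outside
the ROI *or on the mesh's topological border* — the latter keeps the system
non-singular when an ROI reaches the mesh edge. Systems are solved by
biconjugate gradient from a zero initial guess (relative residual 1e-8 by
default, cap 1000 iterations; on the default ~20k-vertex fixture the x
component converges in about 106 iterations at 1e-6), with a direct sparse
factorization as a logged fallback. Solutions overwrite only ROI-interior
values; colors are clipped to [0, 1] after the solve because Poisson
solutions can overshoot.

Two properties follow and are tested: with zero guidance the interior obeys
the discrete maximum principle, and with guidance equal to the target's own
values the output is the target (identity cloning).

**What severity survives the stitch?** The Dirichlet condition adapts the
insert to the recipient: stitched onto a *different* person, the harmonic
correction induced by the boundary mismatch projects onto `u₁` and the
recovered λ̂ can deviate substantially from the λ requested. That is the
blending working as intended, not a solver defect (the interior equations
are satisfied to 1e-10). The meaningful recovery experiment mirrors the
severity sweep on the *same patient*: stitching onto the patient's own
pre-operative reproduced face recovers λ = 0.5 to within ±0.1 (exactly 0.5
in the noise-free, same-topology limit).

# The synthetic study conditions

Real patient scans cannot be shipped, so seeded generators define the study
conditions; every generator is a pure function of its parameters and seed.

* **Reference head** (`make_reference_head()`): a grid-triangulated facial
  shell over azimuth ±1.25 rad and height −110..85 mm, with a superellipse
  radial profile, parametric nose/brow/eye/lip/chin/cheek features, skin
  colors with seeded low-frequency mottle, and the full landmark schema (61
  modeling points — 45 anthropometric, 16 outline — plus 7 mid-face
  validation points, all snapped to vertices) and a 9-ROI polygon table
  (FH, LE, RE, N, LC, RC, M, LN, RN; the chin is absorbed into the mouth
  ROI). The default budget is 20,000 vertices. Two geometric choices keep
  the cylindrical parameterization valid: a mild vertical taper and a 0.15
  forward lean of the face plane, which together keep the cylinder axis
  at least ~15 mm inside the surface at every height after the 10° tilt.
  Distinct individuals come from varying the radius (84–96 mm), feature
  amplitudes (±20%), and a 2 mm low-frequency surface "wobble".
* **Longitudinal series** (`make_longitudinal_series()`): visit `j` adds a
  flap-like bump (Gaussian falloff along vertex normals, truncated at the
  support radius), a discoloration patch over the same support, i.i.d.
  vertex noise (σ = 0.15 mm, a typical stereo-photogrammetry noise floor),
  and global per-channel gain/offset drift. Defaults: 4 visits (pre-op +
  3 post-op, the inclusion criterion of the motivating study), amplitudes
  0/6/9/12 mm, support radius 20 mm centered on the left cheek. The
  20 mm radius keeps the bump's support inside the default cheek+neck ROI,
  consistent with the scenario's premise that the disfigurement is local
  to its ROI — a support crossing `∂φᵢ` would be truncated by the
  Dirichlet condition.
* **Holes** (`inject_holes()`): vertex discs deleted around sampled
  centers, emulating speckle-projection dropouts.

What the generator does **not** emulate: photorealistic skin texture,
population face-space statistics, expression, facial hair, and annotation
error on landmarks (landmarks are exact vertices; annotation error is
studied separately by `perturbation_study()`, which displaces every
modeling landmark by an exact magnitude in a uniformly random direction —
the motivating magnitudes 1.5–3 mm bracket reported human annotation
error). Passing tests on these conditions therefore demonstrate the
machinery — correspondence accuracy, component recovery, seamlessness —
not robustness to everything real scans contain.

# Evaluation machinery

* `validation_error()` scores correspondence with landmarks *not* used by
  the pipeline: 7 mid-face validation points plus 3 peripheral points
  constructed as surface-projected midpoints of modeling-landmark pairs
  (`derive_peripheral_validation_points()`). On 10 synthetic faces at the
  default resolution the maximum per-point mean error is ≈ 1.2–1.4 mm,
  comfortably under the 4.4 mm worst mean reported for the motivating
  clinical data.
* `median_rating()`, `mad_rating()` (median absolute deviation, no
  consistency constant) and `group_median()` summarize observer ratings;
  the group median is operationalized as the median of per-case medians,
  the only reading that reproduces all published group values
  (7.25 real, 1.75 exaggerated, 6.5 peripheral). The published pooled
  mid-face value 5.5 matches the female-target block only (pooling both
  genders gives 5.25); the package exposes the filters and the tests pin
  the female-block reading.
* Ordinal mixed-effect modeling of ratings is deliberately out of scope:
  standard ordinal-regression software handles it and it is not part of
  this package's contribution.

# Numerical choices and problem sizes

* Units are millimetres and color floats in [0, 1]; 8-bit only at I/O.
* Quantiles: type-7 (linear interpolation), deterministic.
* Point-in-polygon: even-odd rule; points on an edge count as inside.
* TPS: ridge `1e-8 × mean(K)` added only when the bordered system is
  ill-conditioned (near-coplanar controls), with a warning.
* Degenerate inputs fail loudly: duplicate TPS controls, collinear
  Procrustes configurations, identical PCA snapshots, ROIs selecting no
  vertices, Dirichlet systems without boundary rows.
* Test and acceptance problem sizes are the package's chosen desk scale:
  module tests run on 1,500–2,500-vertex heads where the geometry is the
  object under test, and the end-to-end correspondence and solver checks
  run at the default 20,000-vertex study conditions (about 20 s for the
  ten-face correspondence experiment on one CPU).

# Known limitations

* The cylindrical parameterization requires a cropped, roughly frontal
  face; strongly non-star-shaped geometry (ears, full heads, extreme
  occlusions) must be cropped away first.
* Only the first principal component is synthesized (`k = 1`); multi-modal
  disfigurement courses would need more components and a policy for their
  joint severity.
* Nearest-neighbor hole filling is piecewise-constant at the rim; large
  holes fill flat rather than smoothly.
* Severity is only recoverable on recipients whose ROI boundary is
  compatible with the donor's mean face (see the stitching section); on
  novel faces λ acts as a control knob, not a calibrated physical
  magnitude.
* The synthetic conditions are stylized; claims about real scan
  populations require real data.
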