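---
title: "Visual field sign mapping: model, numerics, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Visual field sign mapping: model, numerics, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vfsmap)
```

## The problem and the model

A retinotopic map assigns to each cortical position (x, y) a visual field
position, expressed here as eccentricity r (deg from the center of gaze)
and polar angle θ (deg around it, signed within one hemifield: upper
quadrant positive, lower negative, measured from the horizontal meridian).
Extrastriate cortex contains many small, partial, distorted
re-representations of the hemifield, and adjoining areas typically map the
field with opposite handedness. That handedness — the **visual field
sign** — is the quantity this package computes.

Formally, with the cortex viewed from the pial surface of a (normalized)
right hemisphere with y up, let ∇r and ∇θ be the cortical gradients of the
two interpolated coordinate maps, in deg/mm. The local field sign angle is

λ = clockwise angle from ∇r to ∇θ, in [0, 2π).

An undistorted (conformal) nonmirror image map has λ = π/2; an undistorted
mirror image map has λ = 3π/2; the binary classification is λ ∈ (0, π)
versus λ ∈ (π, 2π), and λ near 0 or π (nearly parallel gradients) is
indeterminate. Because λ is an angle *between* gradients, it is unchanged
by rotations, translations, and rescalings of the cortical coordinates, by
adding constants to θ (i.e., by where the meridians are drawn), and by
rescaling r; only relative receptive field positions enter. Mirroring the
cortex reverses the angle's sense and therefore flips the sign everywhere.
`truth_field_sign()` uses the equivalent Jacobian characterization: the
sign of det ∂(r, θ)/∂(x, y) (negative = nonmirror under this convention),
which the test suite cross-checks against the full pipeline.

## Conventions

All analysis runs in a single presentation: right hemisphere, left
hemifield. `normalize_hemisphere()` reflects left-hemisphere cortical x
about the mid-range of x in the table and leaves (r, θ, φ) untouched — the
per-hemifield angular convention is itself mirror-symmetric, so reflecting
the cortex is the entire normalization. Receptive field ellipses drawn on
the flat hemifield chart are stretched circumferentially by
`flat_correction_factor(r)` = r_rad / sin(r_rad), the exact
azimuthal-equidistant chart factor: radial distances are represented
faithfully by construction, which forces this form; it is 1 at the center
of gaze and π/2 (≈1.57×) at 90 deg.

## Interpolation: kernel, parameters, and the neighborhood decision

Scattered samples are gridded by a distance-weighted sum

ζ_j = Σ_i w(d_ij) z_i / Σ_i w(d_ij),  w(d) = ε + exp(−α d²),

with defaults α = 0.8 mm⁻² and ε = 0.15 (middles of the working ranges
0.6–1.2 and 0.1–0.2), grid spacing 0.25 mm (finer than the 0.5 mm
penetration spacing), and a support mask at 1 mm: cells farther than that
from every datum are not estimated. The weights are positive and
normalized, so every estimated value is a convex combination of the data:
constants are reproduced exactly, values never leave the data range, and a
sampled linear ramp is reproduced exactly wherever the sampling is
symmetric. Increasing ε gives remote points residual weight, pulling each
estimate toward its neighborhood mean — the "stiffness" control.

One decision deserves emphasis. Taken over *all* data points, the ε floor
does not decay with distance, so with several hundred penetrations the
floor term (ε·N) dwarfs the local Gaussian mass (≈ π/α per unit data
density) and the "interpolant" collapses most of the way to the global
data mean — plainly not the described behavior of a surface that follows
the data closely and trims only a few degrees from the peaks. The weighted
sum is therefore taken over the *surrounding* points only: data beyond a
cutoff radius get zero weight. The default cutoff is the radius where the
Gaussian term falls to 2% of its peak (`sqrt(log(50)/α)` ≈ 2.2 mm at the
default α), which keeps the floor local (a genuine stiffener) while making
neighborhood-membership changes between adjacent grid cells numerically
negligible (a datum entering or leaving the neighborhood carries under 1%
of the neighborhood weight). `cutoff = Inf` restores the unbounded sum for
comparison. The kernel itself is configurable (`weight_fun`), since only
its qualitative description — a Gaussian of distance with a width control
and a height/stiffness control — is fixed; the printed α range and the
"half-height radius typically 600 µm" remark are not mutually consistent
under any single kernel, so neither is hard-coded.

Edge behavior follows from the same arithmetic: within roughly the kernel
reach of the support boundary, the Gaussian term is one-sidedly truncated
while the floor is not, so estimates bend toward the neighborhood mean and
gradient *directions* tilt. `kernel_reach()` (default tolerance 1e−4,
≈ 3.4 mm) quantifies that reach, and `interior_mask()` restricts summary
statistics to cells at least that far from any unestimated cell. Summary
statistics of λ quoted anywhere in this package are taken over that
interior.

## Gradients, classification, and shading

Gradients are central differences over ±step/2 rounded to whole cells,
step 0.5 mm by default (matching the 500–600 µm differencing used to
suppress noise); any cell whose stencil touches an unestimated cell is
excluded. Cells where either gradient magnitude falls below 0.5 deg/mm are
flagged indeterminate before classification: λ is a ratio of small
differences and is least reliable where the retinotopic gradients vanish,
notably near a center-of-gaze representation. The displayed shade is
S(sin λ) with S(u) = tanh(k·u)/tanh(k), k = 2.5 — an odd sigmoid saturating
at ±1 — and cells with |shade| below a gray threshold are classed
indeterminate. The threshold defaults to 0.2 for display; the analysis
pipeline uses 0, i.e., the binary mirror/nonmirror "first cut", which is
also what segmentation consumes.

## Parcellation and scoring

`segment_sign_map()` takes 4-connected components of uniform sign
(4- rather than 8-connectivity so that opposite-sign regions cannot tunnel
through a diagonal contact), drops components smaller than `min_area`
(default 2 mm² in the pipeline — half the area of the smallest strip in
the default synthetic world), and traces borders along the cell edges
between opposite-sign labels at half-cell resolution; a single
indeterminate cell between opposite labels contributes the gap cell's
midline instead (`max_gap = 1`), since a strong reversal often lands the
zero crossing of sin λ exactly on one cell. Region labels follow row-major
discovery order, so the labeling is deterministic and independent of
record order. `score_recovery()` reports sign accuracy over cells carrying
a true sign, excluding a 0.5 mm band around the true borders
(indeterminate counts as wrong), the mean and maximum distance from
recovered border vertices to the true border polylines, region counts, and
a per-area majority-sign table. Agglomerating same-sign patches into named
areas is deliberately out of scope: it is an interpretive step, not an
algorithm.

## The landmark warp

Penetration positions marked on the cortex photograph must be carried into
the stained-flatmount frame using 8–12 marker lesions. `fit_warp()` fits a
global affine plus a Gaussian radial kernel per control (bandwidth: median
inter-control distance), solved with moment side conditions so the kernel
weights carry no affine component. Consequences, all tested: every control
is interpolated exactly; controls drawn from an affine (or rigid) map
recover it exactly, with unit Jacobian anisotropy; and far from the
controls the mapping decays to its affine part — the reason a Gaussian
kernel was preferred over the thin-plate kernel (available as
`kernel = "tps"`), whose displacements grow without bound. With one or two
controls the fit degenerates gracefully to a translation or a similarity.
The per-control Jacobian anisotropy is reported as the local-distortion
diagnostic.

## The meridian correction

Receptive field reversals in higher areas occur when the *edge* of a large
receptive field reaches a meridian, before its center does. The
size-dependent correction implemented here pushes each center toward the
nearer meridian (horizontal when |θ| < 45 deg, ties included; vertical
otherwise) by β times the ellipse's half-extent along the circumferential
direction, converted to polar-angle degrees at the center's eccentricity,
and capped so a center can never cross the meridian it approaches. β = 0
is the identity; records at r = 0 are never moved. The original rule was
never printed, so only its documented *consequence* is reproducible, and
that is what the acceptance suite asserts: polar-angle reversals move
toward the meridians, while the field sign borders move by well under one
grid cell even at β = 1 — the correction enters r and θ as a smooth,
θ-monotone shift, which leaves the gradient-reversal loci essentially
fixed.

## The synthetic world

The generator states the conditions the analysis is meant to face, and its
defaults are fixed once:

* **Geography**: five parallel 12 × 2 mm strips with alternating sign
  (V2/DLp/DLi/DLa/MT-like; parameters in
  `inst/extdata/strip_cortex.cfg`), plus a separate conformal (log-polar)
  single-area cortex for the analytic λ = 90°/270° cases.
* **Retinotopy**: eccentricity 2–50 deg linearly along x (periphery to
  ~50 deg, as in the owl monkey maps this emulates); polar angle sweeping
  ±80 deg across each strip, reversing direction at each border —
  reversals short of the meridians, because receptive field *centers*
  rarely reach them. The 2–50 deg range also keeps the eccentricity
  gradient comfortably above the 0.5 deg/mm indeterminacy floor after
  interpolation shrinkage.
* **Sampling**: penetration rows along x at 0.5 mm spacing both ways
  (≥ 4 penetrations/mm²), lattice inclusive of borders; a 10 × 10 mm
  cortex yields 21 × 21 = 441 records. `penetration_budget()` and
  `grid_density()` encode the coverage arithmetic (400 mm² at 0.1 mm →
  40,000 penetrations; 0.5 mm → 4 per mm²).
* **Noise**: independent Gaussian receptive field scatter applied in
  flat-chart visual field coordinates (deg), since the experimental error
  budget (~1 deg back-projection accuracy plus biological scatter) is
  expressed in r–θ; 2 deg is the stressed setting. Inter-penetration noise
  correlation is unknown and assumed absent. Receptive field sizes follow
  l = 2 + 0.15·r deg (width 0.7·l, circumferential orientation) — invented
  but configurable values used only for ellipse rendering and the meridian
  correction, never for sign truth.
* **Seeding**: every random draw flows from one recorded seed; identical
  seeds reproduce tables bit for bit.

What a green synthetic test establishes: that the pipeline recovers known
alternating-sign geometry, borders to sub-cell accuracy, and all the
stated invariances, at realistic sampling density and scatter. What it
does not establish: performance under correlated (sheet-wise) digitization
errors, genuinely curved or interdigitated borders, non-monotone
retinotopy within an area, or the areal *naming* problem.

## Numerical and testing choices

* Grid origin derives from the data bounding box (padded by the support
  radius) without snapping, so translated data yield cell-identical runs.
  Cell-exact invariance tests use transforms under which the lattice maps
  onto itself — dyadic translations, quarter-turn rotations, and scalings
  with the mm-denominated parameters (α, spacing, support radius, cutoff,
  step, gradient floor) scaled along. Arbitrary rotations are asserted at
  the gradient level, where λ's invariance is exact; an axis-aligned grid
  only maps onto itself under its symmetry group, and ulp-level ties at
  the support/cutoff thresholds would otherwise flip a handful of
  boundary cells.
* Ties: the meridian correction sends |θ| = 45 toward the horizontal
  meridian; `phi` is reduced modulo 180 on entry; point-in-polygon counts
  boundary points as inside, and the first area in the list claims shared
  borders.
* Degenerate inputs: empty tables read and write cleanly; an all-constant
  field contours to nothing; an everywhere-unsupported field renders an
  empty drawing with a warning; an all-indeterminate map scores as
  "accuracy undefined" rather than zero.
* Serialization is plain text throughout (tables, grid matrices, warp
  sidecars, run configs), written at full precision (`%.15g`) so
  round-trips are exact.

## Known limitations

The analysis is strictly 2-D (physical flatmounts, not surface meshes);
polar angle is interpolated as a plain scalar, which is adequate within
one hemifield (|θ| ≤ ~100 deg) but would wrap incorrectly across a full
360 deg field; the ε-floor kernel, while faithful to its description, is
one of several plausible readings and is therefore swappable; and border
tracing reports polylines between opposite-sign labels only — borders
against unresponsive or indeterminate cortex are support edges, not areal
borders, and are not claimed as such.
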