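---
title: "Hierarchical template matching for cardiac motion and strain: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical template matching for cardiac motion and strain: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(htmotion)
```

## The problem

Tagged MRI imprints a periodic intensity grid on the myocardium that deforms
with the tissue, making intramural motion visible in short-axis cine
sequences. Tracking material points through the cardiac cycle yields the
local deformation gradient and from it circumferential and radial strain —
clinically meaningful measures of regional contractile function. The
difficulty is that widely used non-rigid registration methods (B-spline
free-form deformation in particular) depend on tunable parameters and a
regularisation functional, so a parameter set that registers one image pair
well may fail on the next pair of the same cycle.

`htmotion` implements an alternative that needs no regularisation term and no
per-pair tuning: dense point correspondences from a hierarchical normalized
cross-correlation (NCC) cascade, blended into a smooth non-rigid mapping by
the landmark-based Local Weighted Mean (LWM) transform, applied sequentially
over the cycle, with Eulerian strain computed from the tracked trajectories.

## The matching cascade

The moving image is decomposed into a fixed four-level hierarchy: 16 px
**templates**, each containing four 8 px **segments**, sixteen 4 px
**chunks** and sixty-four 2 px **windows** (`part_grid()`). The first pixels
of all windows form a dense uniform lattice of spacing 2 — the moving point
set. Matching proceeds coarse to fine (`htm_correspondences()`):

1. each template is matched by NCC against a search area around its own
   location in the reference image;
2. centred overlap sections of sizes 14, 12, 10 px chain NCC refinements
   that shrink the matched region while re-localising it;
3. segments are matched inside their template's matched region, followed by
   a 6 px overlap refinement, then chunks inside segments and windows inside
   chunks.

NCC is computed with running-sum (summed-area-table) local statistics
(`ncc_map()`), so normalisation costs one pass over the search region; the
correlation coefficient is invariant to affine intensity changes, which is
what makes the method robust to tag fading. Offsets where either patch has
zero intensity variance are undefined and flagged degenerate rather than
propagating NaN — flat blood-pool and background windows hit this
constantly.

### Search geometry

Child parts are searched in a small area centred on their *expected*
position — the child's offset within its moving parent applied to the
matched parent region (undoing the centring of overlap sections, so corner
segments are reachable) — extended by `overlap_margin` (default 2 px) on
every side. Two considerations fix this geometry:

* the margin bounds how far a child may move relative to its parent between
  consecutive frames; at physiological strain rates this relative motion is
  a small fraction of the part size, well under 2 px;
* on a periodic tag pattern a patch matches the location one tag period
  away almost as well as the true one. Keeping the search smaller than the
  tag period (spacing minus the accumulated motion) makes this failure mode
  geometrically impossible below the template level.

The template level itself uses `template_search_radius` around the
template's own position: 8 px by default for standalone pair registration,
but 2 px in `htm_track()`, because between consecutive phases of a gated
cine sequence motion rarely exceeds a couple of pixels and a search radius
beyond half the tag spacing invites tag jumping at the top of the cascade,
which no lower level can repair.

### Ambiguity, ties and confidence

A 2 × 2 window has four samples; any window whose content is an affine image
of the template's correlates at exactly 1. Along the edge of a flat region
whole families of such windows exist, and near-planar patches separate
competing offsets by less than the correlation's information content.
`best_match()` therefore resolves offsets within a small tolerance of the
peak towards the position the parent level predicts; the tolerance scales
with patch size as `2 / sqrt(npix)` (`peak_tolerance`, default 0.04 at the
window level) mirroring how the sampling noise of a correlation coefficient
shrinks with the number of samples. Exact floating-point ties are broken
deterministically (smallest row, then column) so results are reproducible.

Confidence flags are strict: a window is excluded from the transform fit
(`flag != "ok"`) if its own match is degenerate, if its peak is tied or on
the search border (the true optimum may lie outside), or if *any* ancestor
in its cascade chain fell back to a guessed position — a search centred on a
guess produces confident-looking matches that are silently wrong.

### Sub-pixel localisation

Integer matching of sub-pixel inter-frame motion cannot work over a long
sequential chain: neighbouring windows share the same rounding of the
smooth displacement field, so averaging recovers nothing and the rounding
error accumulates as a coherent drift. The cascade therefore refines the
correlation peak to sub-pixel precision by fitting a bivariate quadratic to
the 3 × 3 neighbourhood of the peak (`subpixel_peak()`); the full 2-D fit
matters because twist shears the peak diagonally. The refinement is only
meaningful where the peak has usable curvature: an 8 × 8 segment localises
this way to better than a tenth of a pixel, while a 2 × 2 window cannot.
Each window's final reference position is consequently anchored to its
segment's refined displacement; the window- and chunk-level matches are
retained as consistency checks and flag sources. An exact peak
(correlation 1 to rounding) is never refined, so integer translations are
recovered exactly.

## The Local Weighted Mean transform

Given `N` control-point pairs, `lwm()` fits, for every control point, a
bivariate degree-2 polynomial (6 monomials) over the point and its `n - 1`
nearest neighbours — exact interpolation at `n = 6`, least squares above.
The transform at an arbitrary point is the weighted mean of all local
polynomials whose support reaches it, with the compactly supported cubic
weight `W(D) = 1 - 3D² + 2D³` on `D = distance / D_n`, where `D_n` is the
distance from the polynomial's centre to its `(n-1)`-th neighbour. `W` and
its derivative vanish at `D = 1`, so the blended field is continuously
differentiable, and no global system of equations is ever solved — every
fit involves `n` points only, which keeps the transform local and fast.

Defaults and degenerate cases:

* `n = 12`: six points barely determine a quadratic and are easily
  ill-conditioned; twelve give a comfortably overdetermined local fit.
  `n < 6` is refused outright.
* Local designs are centred on their control point before solving, and
  their conditioning is estimated from the singular values; a condition
  number above `1e8` degrades that fit to affine with a warning
  (near-collinear neighbourhoods occur on lattice control points).
* A query beyond every support radius has zero total weight. This is an
  error by default; `extrapolate = TRUE` (used by the tracking pipeline)
  evaluates the nearest polynomial instead and flags the point, because a
  silently wrong extrapolation would corrupt strain downstream.

## Sequential tracking and inverse consistency

`htm_track()` registers consecutive pairs `I_k -> I_{k+1}`, fits an LWM
transform to the confident correspondences of each pair and pushes the
tracked positions through it; a 19-phase cycle is 18 registrations. By
default each pair is registered in both directions and the transform fitted
to the union of forward pairs and inverted backward pairs. The leading
error of the peak localiser is an odd function of the sub-pixel
displacement, so the two directions cancel it; without this the small
per-pair bias compounds over the chain into a drift that never averages
away. On the built-in phantom the cycle-end tracking error returns almost
to zero, as a cyclic motion demands.

## Strain

Displacement is always taken relative to the first frame, `U = L - L₁`. The
displacement gradient `∂U` is estimated per point by a local least-squares
plane fit of each displacement component over the tracked points within
`radius` (default 8 px) of the point in its *current* position — tracked
points deform off-lattice, so gridded finite differences do not apply, and
differentiating with respect to deformed coordinates is the reading under
which `F = (I - ∂U)⁻¹` and the Almansi strain
`E = ½[I - (FF^T)⁻¹]` are the standard self-consistent Eulerian
definitions (rigid motions then give exactly `E = 0`). Points with fewer
than three non-collinear neighbours are flagged and excluded rather than
guessed.

`E` is projected onto the radial unit vector (centroid to point) and its
90°-rotation to give `E_rr` and `E_cc`. Points are assigned once, from
their frame-0 positions, to the six standard AHA sectors — Anterior,
Anteroseptal, Inferoseptal, Inferior, Inferolateral, Anterolateral — in 60°
counter-clockwise sectors starting at `reference_angle` (half-open, so a
boundary point belongs to the sector it begins). Regional curves are
unweighted means over each region's valid points; frame 0 is identically
zero. The angular origin is anatomy (the anterior RV insertion) and cannot
be derived from a single slice, so it is a required input for real data;
the phantom uses 90° ("up").

## The synthetic phantom

`tag_phantom()` renders an annular myocardium (inner radius 18 px, outer
40 px in a 128 × 128 frame at 1.48 mm/px — a typical adult LV short-axis
at a typical scanner resolution) carrying a SPAMM-like multiplicative
`cos²` tag grid of 6 px spacing, over a 19-phase cycle. Motions with
closed-form ground truth: translation (linear ramp), rigid rotation,
uniform scaling, and the default contraction + twist, where a material
point at radius `r` maps to `α(t)·r` and rotates by
`τ(t)·(r - r_in)/(r_out - r_in)` — peak contraction `α = 0.85` and peak
twist 8°, both following the cyclic profile `sin²(πt/(T-1))` that peaks at
mid-cycle and closes the cycle. The analytic Jacobian of this map provides
per-point ground-truth Almansi strain (peak `E_cc ≈ -0.19`, within the
range reported for healthy human LV).

Rendering inverts the motion in closed form per pixel and evaluates the
material pattern analytically, so tags are advected exactly, with no
resampling error. The tag grid is multiplied by a smooth low-frequency
material-attached shading (a stand-in for coil sensitivity and tissue
heterogeneity): a *perfectly* periodic grid is ambiguous under translation
by one period for any matcher, which is an artefact of idealised synthesis,
not a property of real acquisitions. Optional per-frame tag fading and
seeded additive Gaussian noise emulate the main tag-MRI degradations.

What the phantom does **not** emulate: MRI physics (k-space, SSFP signal,
bias fields beyond the smooth shading), through-plane motion, papillary
muscles, surrounding anatomy, and inter-subject variability. Passing the
phantom validates the geometry and numerics of the pipeline — it does not
certify accuracy on clinical images, where noise, anatomy texture and
through-plane decorrelation dominate.

Validation scales: the test-suite phantom runs at 64 × 64 with 3 frames for
unit checks and the full 128 × 128, 19-frame cycle (about 650 mid-wall
sample points, 18 withheld landmarks on 3 rings × 6 sector centres) for the
end-to-end checks; the latter completes in roughly two minutes in the
suite, and the acceptance script repeats it from scratch.

## Evaluation harness

`tre()` computes per-frame RMSE between tracked and true landmark
positions, in px and mm, pooling mean ± SD over the tracked frames —
landmarks live off-lattice by construction and are never control points.
`compare_models()` performs the paired comparison used to benchmark one
tracker against another: mean errors, the second model's error as a
percentage of the baseline, the percentage reduction, and a paired t-test;
a zero-variance difference vector reports the exact reduction with the
test flagged degenerate instead of emitting infinities.

## Known limitations

* Purely 2-D: through-plane motion is invisible and longitudinal strain out
  of scope.
* Sequential composition: per-pair errors compound; the inverse-consistent
  fit removes the systematic part but the random part still grows with
  cycle length.
* The hierarchy is fixed at 16/8/4/2; images smaller than 16 px per side
  cannot be processed and border strips narrower than 16 px are excluded
  from matching.
* Strain quality depends on seed density: the moving-least-squares gradient
  needs several valid neighbours within its radius, so sparse seeding
  degrades `E` before it degrades tracking.
* No segmentation: the myocardial mask, centroid and reference angle are
  caller-supplied inputs on real data.
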