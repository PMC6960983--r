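---
title: "Measuring grain thickness from stereo edge features"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring grain thickness from stereo edge features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grainstereo)
```

## The measurement problem

Grain length and width are routine 2-D image measurements; thickness — the
dimension perpendicular to the surface a grain rests on — is not, because it
requires depth. Classical binocular stereo recovers depth by matching
corresponding points between two views, but a grain's surface is smooth,
translucent and essentially textureless, so there is nothing for a
texture-based matcher to lock onto at the crown of the grain, which is
exactly where the thickness lives.

`grainstereo` implements a two-part escape from this impasse:

1. **The half-thickness hypothesis.** A grain of thickness $H$ lying on a
   flat board presents its occluding silhouette rim at some height $h$ above
   the board. Because grains have a "front" and a "back" side, $h$ is not
   exactly $H/2$: front-side-up grains show the rim at $h$, back-side-up at
   $H - h$. Writing $h = H/2 - \delta$, a fair coin decides which side lands
   up, so over many randomly dropped grains
   $$\mathbb{E}[\text{rim height}] = \tfrac12 h + \tfrac12 (H-h) =
   \tfrac12 H ,$$
   and thickness can be estimated as **twice the mean rim height** over the
   population. The target moves from the (unmatchable) crown to the
   (matchable) silhouette edge.

2. **Shape-based edge correspondence.** The rim itself also lacks texture,
   but it has *shape*. For each segmented grain the boundary is expressed as
   a polar-distance profile $h(\theta)$ — the centroid-to-edge distance
   resampled by linear interpolation at 1° steps, giving a 360-vector. The
   feature vector of edge point $i$ is the profile rotated to start at
   angle $i$, so matching the two views' edge points reduces to finding the
   circular shift $k$ maximising the Pearson correlation between the left
   profile and the right profile rotated by $k$. Left angle $i$ then
   corresponds to right angle $(i + k) \bmod 360$.

Matched edge-point pairs are triangulated by photogrammetric space
intersection, each grain contributes the mean of its 360 reconstructed
heights, and the report is $2 \times$ the mean over grains.

## Geometry: collinearity, resection, intersection

The camera model is the classical photogrammetric pinhole. With rotation
$R(\varphi, \omega, \kappa) = R_\varphi R_\omega R_\kappa$ (rotations about
the Y, X and Z axes, in that order) and projection centre $S = (X_s, Y_s,
Z_s)$, an object point $P$ maps to photo coordinates through the
collinearity equations
$$x - x_0 = -f \, \frac{r_1 \cdot (P - S)}{r_3 \cdot (P - S)}, \qquad
  y - y_0 = -f \, \frac{r_2 \cdot (P - S)}{r_3 \cdot (P - S)},$$
where $r_i$ are the rows of $R$ and $(x_0, y_0, f)$ the interior
orientation in pixels.

* **Space resection** (`space_resection()`) recovers the six exterior
  parameters of one camera from the circle-grid control points by
  Gauss–Newton least squares with a numerical Jacobian and step halving;
  convergence when the largest update drops below $10^{-8}$, cap 100
  iterations. The default initial value is a nadir attitude above the
  control centroid with $Z_s$ from the board/image scale ratio — adequate
  for any near-nadir rig.
* **Space intersection** (`space_intersection()`) solves the four
  collinearity equations of a corresponding pair for $(X, Y, Z)$: the
  equations are rearranged into a linear $4 \times 3$ system solved by
  least squares, followed by one Gauss–Newton step on the reprojection
  residuals. The implementation is vectorised over points (a grain's 360
  pairs are intersected in one call).
* **Lens distortion** uses the Brown–Conrady model (radial $k_1, k_2, k_3$,
  tangential $p_1, p_2$) on coordinates normalised by $f$. Observed points
  are undistorted by fixed-point iteration to $10^{-6}$ px. Points
  (centroids, boundary samples) are undistorted rather than resampling the
  whole image: downstream of segmentation the two are equivalent and the
  point route is far cheaper.

Raster indices are R's native 1-based `(row, col)` with the origin at the
top-left pixel centre; photo coordinates are centre-referenced, x right and
y up: `x = col - (width + 1)/2`, `y = (height + 1)/2 - row`. The
principal-point offset enters only through the collinearity equations, so
the raster conversion stays a pure recentring and the bijection is trivial
to test.

## Control points from the board

The background board carries a grid of bright circles of known radius and
spacing; the corner circle is the object-space origin, the long side the X
axis, the board plane the datum $Z = 0$. Detection is Otsu thresholding,
8-connected components, an area gate of $[0.5, 2] \times$ the expected
projected circle area and an intensity-weighted centroid — sub-0.1 px on
rendered boards. Grid ordering clusters the detections by row and column
coordinate; cells are numbered so that the grid row index increases along
+Y, which for a near-nadir camera with small $\kappa$ runs from the bottom
of the displayed image upward. Circles partially covered by a grain simply
drop out; resection is overdetermined and the missing cell is reported.

## Segmentation

The extraction chain follows the standard recipe: luma graying
($0.2989R + 0.5870G + 0.1140B$), 3×3 median denoising (edge-replicated; the
3×3 path uses the exact column min/median/max decomposition for speed),
Otsu binarisation (exhaustive between-class-variance scan over a 256-bin
histogram), 8-connected labelling, and an area gate that removes broken
fragments and clumps of touching grains. Area limits default to
$[0.2, 3] \times$ the median component area — self-scaling, since absolute
pixel areas depend on the rig — and explicit limits override. The
calibration circles are bright like the grains, so the circle components
found during orientation are masked out of the grain candidates. Boundaries
come from Moore-neighbour tracing with Jacob's stopping criterion, oriented
counter-clockwise in the photo frame, holes filled first.

## Matching details and numerical choices

* **Grain correspondence.** Each right-image grain's centroid ray is
  intersected with the board plane to approximate its position, projected
  into the left image, and paired with the nearest left centroid (greedy
  one-to-one, nearest first; the gate defaults to half the minimum left
  inter-centroid distance). Using $Z = 0$ instead of the unknown rim height
  displaces the projection by well under a millimetre at desk scale, far
  below the inter-grain spacing.
* **Profile resampling.** Raw polar samples are sorted by angle; where
  rasterisation makes an angle multivalued the outermost crossing is kept
  (silhouettes are near-convex). An angular gap above 20° aborts with an
  error — it signals a boundary the star-shaped model cannot represent.
  Profiles interpolate circularly, so angle 359.5° uses the wrap to 0°.
* **The 180° ambiguity.** A centrally symmetric silhouette makes
  $h(\theta)$ exactly 180°-periodic, so the correlation argmax ties between
  $k$ and $k + 180$; picking the wrong branch matches diametrically
  opposite rim points and wrecks the triangulation. `measure_thickness()`
  therefore re-evaluates every shift whose correlation is within
  `shift_tie_tol` (default 0.01) of the maximum and keeps the one with the
  smallest mean reprojection residual. This uses only the stereo geometry
  already in hand — no epipolar machinery — and is a no-op for clearly
  asymmetric outlines.
* **Zero-variance profiles** (perfect circles) cannot be matched by shape;
  they are flagged and the pair is skipped.
* **Aggregation.** Per-grain mean first, then mean over grains, then ×2, so
  every grain carries equal weight regardless of boundary length. Negative
  reconstructed heights are kept; clamping would bias the noise
  distribution. Residual-based point rejection exists
  (`residual_cap`) but is off by default, reproducing the plain mean.

## The synthetic scene generator

`sample_scene()` / `render_stereo()` emulate the physical experiment:
elliptical grains (default semi-axes 3.2–3.8 mm × 1.1–1.4 mm, thickness
1.8 mm) are dropped without silhouette overlap on a 3×4 circle-grid board
(30 mm spacing, 4 mm radius), each flipped by a fair coin so its rim plane
sits at $H/2 \pm \delta$ (default $\delta = 0.15$ mm). Two cameras 350 mm
above the board with an 80 mm baseline (base–height ratio ≈ 0.23, inside
the ratio window that balances occlusion against intersection conditioning)
image the scene at ≈ 0.1 mm/px through a 3500 px principal distance. The
renderer projects each grain's rim ellipse analytically, anti-aliases by
sub-pixel sampling, then applies 0.5 px Gaussian blur and additive gray
noise ($\sigma = 2$ gray levels by default). All randomness is seeded.

Two deliberate simplifications, and what they imply:

* **Flat-rim grains.** A grain is represented by its rim ellipse at a
  single height; the domed upper surface is not modelled. Consequently the
  upward bias reported on real grains — segmentation erodes the silhouette
  onto *higher* surface points, so calculated values tend to exceed caliper
  values — cannot appear here: with a planar rim, equal radial erosion in
  both views shifts both image points identically and cancels in the
  intersection (we verify this erosion-invariance in the tests). Passing
  synthetic tests therefore validates the geometry, matching and
  statistics, but not robustness to surface-curvature bias on real
  imagery.
* **Rig pointing.** The default cameras point straight down (parallel nadir
  axes). A nadir view maps the board plane by a similarity, so polar angles
  about a grain's centroid are *identical* in the two views and the shape
  correspondence is exact. A convergent rig
  (`default_rig(convergent = TRUE)`) is supported; its mild projective
  anisotropy perturbs the angle correspondence by a fraction of a degree
  and adds per-grain height systematics of a few hundredths of a
  millimetre — measurable with this package, and a useful reminder that
  the method's accuracy is geometry-dependent.

At 0.1 mm/px the dominant per-grain error is boundary rasterisation phase
(a few hundredths of a millimetre per grain, zero-mean); it averages out
across grains, leaving scene-level estimates within ~0.01 mm of the
flip-limited optimum $2\,\overline{\text{rim}_z}$.

## What the estimator can and cannot promise

The irreducible scene-level error is the flip average: with $n$ grains of
rim offset $\delta$, the estimator's standard error is $2\delta/\sqrt{n}$
(0.067 mm at $n = 20$, $\delta = 0.15$ mm). Any single scene can therefore
land outside a fixed tolerance with non-trivial probability even when the
pipeline is exact; what shrinks with effort is the *spread*, at the
$1/\sqrt{n}$ rate, which the sample-size sweep verifies. Around ten grains
the band passes under the 0.1 mm industry tolerance, matching the usual
ten-sample recommendation for image-based grain sizing.

## Problem sizes used by the test-suite and acceptance runs

Unit tests of detection, ordering and matching mechanics run on a compact
rig (3×4 board at 24 mm spacing, 0.18 mm/px) where scenes render in well
under a second; accuracy-sensitive checks (resection recovery, single-grain
accuracy, erosion invariance, the end-to-end error bound) run at the full
study geometry above. The headline end-to-end check measures 50 seeded
scenes of 20 grains; the sample-size sweep uses 12 seeds at each of
$n \in \{2, 5, 10, 20\}$ — enough to estimate the spread at each size while
keeping the whole suite inside a coffee break.

## Known limitations

* Star-shaped boundary assumption: strongly concave silhouettes (broken or
  malformed grains) are rejected by the gap guard rather than measured.
* Touching grains are removed by the area gate, not split; heavy clumping
  reduces the usable sample.
* Per-grain thickness on real data is not meaningful — the hypothesis is
  population-level; single-grain numbers carry the unknown $\pm\delta$.
* Epipolar-constrained matching is deliberately out of scope; the circular
  correlation search is the method under study.
* The real-imagery surface-curvature bias is documented but not corrected;
  no correction is established for it.
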