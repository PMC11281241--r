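---
title: "Separating touching pods with a structured-light scan: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Separating touching pods with a structured-light scan: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(podsplit3d)
```

## The problem

Pod-shaped objects such as peanut pods defeat classical 2D instance
segmentation when they touch: their silhouettes merge into one connected
component, their shells are heavily textured, and the five shape classes
(common, axe, cocoon, wasp-waist, lollipop) are far from round, so
watershed-style splitting over- or under-segments them. `podsplit3d`
implements a multimodal strategy: recover the 3D shape with a
line-structured-light scan, split the *cloud* where the surface geometry
changes, and carry each pod's 2D contour back into the image as a matching
template.

The pipeline is:

1. **Reconstruction** — per frame, the laser stripe centerline is extracted
   and triangulated against the calibrated light plane; frames are spliced
   along the guide axis by the displacement $d = v\,t$.
2. **Cloud segmentation** — per-point normals and surface-variation
   curvature by local plane fitting; curvature-seeded region growing splits
   the cloud at the creases between touching pods.
3. **Contour extraction** — each pod region is projected to the table plane
   and its boundary extracted with the rolling-ball (alpha-hull) rule, then
   ordered and rasterized into a binary template.
4. **Template matching** — a gradient-direction shape model searched
   coarse-to-fine through an image pyramid, refined to sub-pixel accuracy by
   a linear least squares in $(\theta, x, y)$, the matched region filled and
   repaired with a morphological opening.
5. **Evaluation** — per-object pixel accuracy $P = 100\,K_1/K_2$ and the
   pixel-weighted mean success rate
   $\sigma = 100\,\sum_i z_i / \sum_i Z_i$.

## Triangulation model

A pixel $(u, v)$ (column, row; 0-based; pixel centers at integers) defines
the viewing ray $\big((u-u_0)/f_x,\ (v-v_0)/f_y,\ 1\big)$. Intersecting it
with the laser sheet $aX_c + bY_c + cZ_c + d = 0$ gives the closed form

$$Z_c = \frac{-d}{a\,(u-u_0)/f_x + b\,(v-v_0)/f_y + c},$$

after which the point reprojects to $(u, v)$ exactly and satisfies the
plane equation to machine precision; rays within $10^{-12}$ of parallel to
the sheet are rejected. The depth's sign follows the supplied plane
coefficients — with some published calibrations the principal-ray depth
comes out negative, which simply reflects the rig's axis convention, and
both signs are accepted. World coordinates use the closed-form inverse
$X_w = R^\top (X_c - T)$; rotation matrices from physical calibration are
often orthonormal only to $\sim 10^{-3}$, so orthonormality violations
warn instead of failing (the closed form and a numeric $4\times4$ inverse
then differ at the same relative level, which the tests account for).

The stripe centerline is the per-column intensity-weighted centroid of the
pixels above a threshold (gray-gravity center). The threshold trades noise
rejection against a small truncation bias: cutting the stripe's Gaussian
tails asymmetrically biases the centroid by up to a few hundredths of a
pixel. On noise-free synthetic frames the tests therefore use a near-zero
threshold, which brings the flat-table reconstruction error below
$10^{-6}$ mm; on noisy or 8-bit frames the default of 30 (of 255) is
appropriate.

## Surface features and region growing

For each point and its $k$ nearest neighbors (exact, grid-indexed,
distance-then-index tie-broken) the neighborhood covariance $S$ is
eigen-decomposed; the normal is the eigenvector of the smallest eigenvalue
$\lambda_1$ and the curvature is the surface variation
$\rho = \lambda_1 / (\lambda_1+\lambda_2+\lambda_3) \in [0, \tfrac13]$.
Normals are sign-flipped toward the camera (+Z) for output consistency, but
all angle tests use unoriented normals ($\arccos|n_1\!\cdot\!n_2|$), so the
arbitrary PCA sign can never split a region.

Region growing follows the classic two-tier rule: the globally
lowest-curvature point seeds a region; a neighbor *joins* when its normal
is within `angle_thresh` of the **current seed's** normal, and a joined
point is *promoted* to a seed only when its own curvature is below
`curv_thresh`. Seeds are processed FIFO and global seeds taken in
(curvature, index) order, so the algorithm is fully deterministic. Growth
stops when fewer than `min_region` points remain; undersized regions join
the residual. The function-level defaults ($k=30$, $15^\circ$, $0.05$,
`min_region` 100) are conventional general-purpose values.

**Why the pipeline uses tighter thresholds.** Two touching convex pods
meet in a parabolic wedge. Near the tangent point the two visible walls
are nearly vertical and their unoriented normals approach each other: for
sampling step $\Delta$ across the crease the minimal cross-pod normal
angle scales as $\sqrt{2\Delta/\rho_{\mathrm{lobe}}}$ (about $13$–$15^\circ$
at $\Delta = 0.3$–$0.4$ mm for 11 mm lobes). A raw stripe scan is also
strongly anisotropic (0.1 mm along the guide, ~0.35 mm across), which
creates much closer cross-pod pairs along the guide axis. The pipeline
therefore (a) voxel-downsamples the cloud to 0.4 mm before feature
estimation, restoring isotropy and keeping the worst-case cross-pod angle
near $15^\circ$, and (b) grows with `angle_thresh` $=12^\circ$ and
`curv_thresh` $=0.02$ — comfortably above the on-pod values
($\lesssim 2^\circ$ between neighboring normals, $\rho \sim 10^{-3}$ even
with shell texture) and below the crease values. These numbers follow from
the geometry above, not from tuning against the test suite, and they are
plain arguments of `segment_cloud_to_templates()`.

The elevation pre-filter (`z_window`, default keep $z \ge 2$ mm) strips the
table return before segmentation.

## Rolling-ball boundary and contour ordering

A pair $(A, B)$ with $|AB| \le 2r$ is a boundary edge iff one of the two
radius-$r$ circles through $A$ and $B$ contains no other point strictly
inside. "Strictly" means closer than $r - \varepsilon$ with
$\varepsilon = 10^{-9} r$, so points exactly on a circle never block an
edge, and the chord $|AB| = 2r$ needs no special case
($D = \sqrt{\max(0, r^2 - L^2/4)}$ makes the two centers coincide).
Candidate pairs and interior tests are restricted by a uniform-grid index;
a brute-force $O(M^3)$ oracle in the test suite confirms exact edge-set
equality. The default radius is $3\times$ the median nearest-neighbor
spacing of the projected points.

The boundary edges are ordered by tracing the **outer face** of the edge
graph: starting from the bottom-most vertex, the walk always takes the
most counter-clockwise edge relative to its arrival direction (reversing
only at dead ends). This is linear-time, deterministic, and returns the
largest closed loop by construction; a greedy smallest-turning-angle walk
was tried first and proved fragile on dense alpha-shape graphs, where
failed partial walks consume edges of the outer ring. The polygon is
normalized counter-clockwise and rasterized as a 1-pixel-wide Bresenham
contour on a cell grid (`mm_per_pixel` cells, origin recorded so pixels map
back to millimeters exactly).

## Shape model and matching

Template preprocessing: threshold, 1-px morphological closing (connects
adjacent fragments), hole filling by border flood (the outline is
8-connected, so background flood with 4-connectivity is the correct dual),
connected components, an area filter that must leave exactly one component,
and an outer-contour trace. Contour points are pushed half a pixel outward
along their normals — the traced contour runs on foreground pixels while
image gradients peak on the intensity step between foreground and
background, and without this correction the matching and refinement carry a
systematic ~0.4 px radial bias. Normals come from central differences on a
lightly smoothed trace (staircase suppression) and are oriented outward by
a centroid majority vote. The model holds up to 512 points at the finest
pyramid level, halving per level (floor 8), with the angle step doubling
per coarser level.

The similarity of a pose is the mean over model points of
$|\cos\angle(\mathrm{R}n_i,\ g(\mathbf{W}p_i))|$ — the polarity-tolerant
normalized gradient-direction score in $[0,1]$. The coarsest level is
scanned exhaustively over translations for every (angle, scale) on the
grid; local maxima above a relaxed threshold are tracked down the pyramid
with a $\pm2$ px, $\pm1$ angle-step, $\pm\tfrac12$ scale-step local search
per level; greedy non-maximum suppression limits pairwise bounding-box
overlap.

Pose refinement minimizes the sum of squared point-to-tangent distances
$\big[(\mathbf{W}m_i - e_i)\cdot n_i\big]^2$ over the linearized rigid
update $(\delta\theta, \delta x, \delta y)$ (small-angle form of the
rotation), a 3-unknown linear least squares iterated with re-matching.
Correspondences are the nearest edge points along each transformed model
normal (sub-pixel Sobel/NMS/hysteresis edges; candidates within 5 px,
preference to those within 1.5 px of the normal ray). Scale is held fixed
during refinement — the discrete scale sweep of the search already covers
it. An iteration that would raise the mean absolute residual is rolled
back and refinement stops, which guarantees the monotone residual descent
the tests assert; convergence is declared below $10^{-3}$ px/radian.
Known shifts up to 3 px are recovered within 0.1 px and rotations up to
$3^\circ$ within $0.3^\circ$ on the test geometry.

The matched region is the filled interior of the pose-transformed model
contour, then repaired by a morphological opening with a disk structuring
element (anti-extensive and idempotent; note that a *disc* opening rounds
the corners of a perfect square by a pixel — exact invariance holds for
disc-shaped masks, which is what the tests assert).

## The synthetic scene generator

No public capture-rig data exist for this problem, so the generator is a
first-class module that emulates all three modalities with known ground
truth.

**Pods.** A pod is a surface of revolution: spherical lobe caps of radii
$r_1, r_2$ joined by a Hermite radius blend over the lobe separation,
multiplied by a Gaussian-window waist pinch (factor `waist` at the middle,
width `sep/4`) and by a sinusoidal radius modulation standing in for shell
texture. The five morphology presets use lobe radii 7–13 mm and lengths
30–45 mm, typical of real pods. The pod rests on the table (axis height =
maximal effective radius) and is posed by a 2D position and yaw; full 3D
tumbling is out of scope. With equal lobes, zero separation and no pinch
the surface degenerates to an exact sphere, which the tests exploit.

**Scan rig.** Camera 500 mm above the table looking straight down
(extrinsics $R = \mathrm{diag}(1,-1,-1)$, $T = (0,0,500)$), $f = 2000$ px,
a $64 \times 700$ sensor ROI, and a *vertical* laser sheet offset 55 mm
from the nadir; the lateral offset is the triangulation baseline (depth
resolution $\approx 2$ mm/px at the table — adequate here because the
acceptance scans are noise-free; `noise_px` jitters the stripe center when
sensitivity analyses want it). Guide speed 0.1 mm/s with one frame per
second, i.e. 0.1 mm splice spacing. Per frame the sheet's intersection
with the scene's upper envelope is sampled densely in $x$, projected
through the pinhole model, and reduced to one stripe point per camera
column by **minimum camera depth** — which is exactly how mutual occlusion
between tall neighboring pods manifests on a real rig. The stripe is drawn
as a Gaussian profile ($\sigma = 1.2$ px, window $\pm 8$ px, exact zeros
outside), so the noise-free centroid is exact to $\sim10^{-9}$ px.

**Renderer.** Orthographic top-down shading from the analytic surface
normal (`0.40 + 0.55 nz^{1.5}` at unit illumination, dark background
0.12), plus seeded additive Gaussian noise. Instance masks come from the
same height fields (each pixel belongs to the highest surface), so they
align with the silhouettes exactly and are disjoint. Scenes are composed
by pushing pods together until their silhouettes overlap by 0.25 mm
(adherent in 2D); configurations interpenetrating deeper than 1 mm in 3D
are rejected.

**What the generator does not emulate:** lens distortion, laser speckle,
inter-reflections, shell color/texture variation beyond the radial bumps,
and pods leaning or stacked on each other. Passing tests therefore
demonstrate the correctness and robustness of the algorithms under
idealized capture, not performance on a physical rig.

## Problem sizes and determinism

The test suite and the acceptance script use: 15-frame table scans and
~520-frame single-pod scans for reconstruction fidelity; a ~20k-point
ideal adherent cloud for region growing (grid spacing 0.26 mm); random
point sets of up to 150 points against the $O(M^3)$ rolling-ball oracle;
and five fixed-seed adherent scenes of 2–4 pods spanning all five
morphologies for the end-to-end check (scan, reconstruct, segment,
contour, match, score; per-pod mask IoU $\ge 0.85$ and $\sigma \ge 90\%$
required, $\approx 0.97$ and $99\%$ observed). Every random quantity is
seeded; generators restore the caller's RNG state.

## Known limitations

* Region separation relies on the crease geometry between touching convex
  bodies; pods interpenetrating much deeper than the sampling scale, or
  scanned at resolutions far coarser than the lobe radius, can merge.
* The 2D matcher assumes the scene is viewed at the same scale as the
  template (a narrow scale sweep absorbs reconstruction error); wildly
  different magnifications need a wider, slower sweep.
* Only the outer contour is modeled — inner holes are ignored by design.
* `score_scene` solves the mask assignment exactly only up to 7 objects
  (exhaustive enumeration), falling back to a greedy match above that.
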