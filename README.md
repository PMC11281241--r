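# podsplit3d

Segmentation of **touching (adherent) pod-shaped objects** — peanut pods
and similar crops — in top-down images, assisted by a line-structured-light
3D scan. When pods touch on a sorting bench their 2D silhouettes merge into
one blob; their non-convex, heavily textured shapes (common, axe, cocoon,
wasp-waist and lollipop types) defeat watershed-style splitting. This
package splits them in 3D instead, and maps each pod back onto the 2D image
by shape-based template matching.

## Method

1. **3D reconstruction.** Per stripe frame, the laser centerline is the
   column-wise intensity-weighted centroid; each centerline pixel `(u, v)`
   is intersected with the calibrated light plane
   `a·Xc + b·Yc + c·Zc + d = 0` via the closed form
   `Zc = −d / (a(u−u0)/fx + b(v−v0)/fy + c)`, transformed to world
   coordinates by `Xw = Rᵀ(Xc − T)` and spliced along the guide axis by the
   displacement `d = v·t`.
2. **Point-cloud segmentation.** Local-plane PCA gives per-point normals
   and the surface-variation curvature
   `ρ = λ1/(λ1+λ2+λ3) ∈ [0, 1/3]`; curvature-seeded region growing (join
   below a normal-angle threshold, promote to seed below a curvature
   threshold) splits the cloud at the creases between touching pods.
3. **Contour extraction.** Each region is projected to the table plane; its
   boundary is the rolling-ball (alpha-hull) edge set — a pair `(A, B)`
   with `|AB| ≤ 2r` is a boundary edge iff a radius-`r` disk through both
   contains no other point — ordered into the outer closed loop and
   rasterized as a binary template.
4. **2D template matching.** A pyramid shape model (edge points + outward
   normals) scored by the polarity-tolerant gradient-direction similarity;
   the best pose is refined to sub-pixel accuracy by iterated linear least
   squares over `(θ, x, y)` on point-to-tangent distances
   `((W·mᵢ − eᵢ)·nᵢ)`; the matched region is filled and repaired by a
   morphological opening.
5. **Metrics.** Pixel accuracy `P = 100·K1/K2` per object and the
   pixel-weighted mean success rate `σ = 100·Σzᵢ/ΣZᵢ`.

A seeded synthetic generator replaces the capture rig: parametric pod
surfaces in the five morphologies, simulated stripe-frame stacks (with
per-column occlusion), and rendered top-down scenes with exact per-pod
ground-truth masks.

## Worked example

```r
library(podsplit3d)

# a two-pod adherent scene: scan -> reconstruct -> split -> match -> score
res <- run_synthetic_pipeline(c("common", "wasp_waist"), seed = 7)

attr(res$segmentation$cloud, "regions")
#>   id size          cx       cy       cz
#> 1  0 8836 21.72203058 83.25429 17.54190
#> 2  1 6877 -0.04280077 84.15739 16.82433

res$score
#> segmentation_score (intersection mode): sigma = 99.84%
#>  truth pred    K1    K2        P       IoU
#>      1    1 15588 15614 99.83348 0.9832219
#>      2    2 17921 17949 99.84400 0.9764616
```

The two touching pods come out as two cloud regions (8836 and 6877 points
after voxel downsampling); matching their contours back into the rendered
scene recovers both instances with IoU ≈ 0.98 against the generator's
ground-truth masks and a mean success rate σ of 99.8%. The per-template
poses are available as `res$matching$matches[[i]]$pose`:

```r
res$matching$matches[[1]]$pose
#> pod_pose: theta 0.16 deg, t (173.68, 194.35) px, scale 1.000, score 0.982
```

Lower-level entry points mirror the pipeline stages: `assemble_cloud()`,
`estimate_normals_curvature()`, `region_growing()`,
`rolling_ball_boundary()`, `order_contour()`, `build_shape_model()`,
`find_matches()`, `refine_pose()`, `open_mask()`, `score_scene()`. A thin
command-line front end with `reconstruct` / `segment3d` / `contour` /
`match` / `evaluate` / `simulate` subcommands lives in
`inst/cli/podsplit3d.R`.

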