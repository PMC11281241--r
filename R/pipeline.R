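#' Segment a reconstructed cloud into per-pod contour templates
#'
#' The 3D half of the pipeline: elevation pre-filter, voxel downsampling to
#' even out the anisotropic stripe sampling, k-NN features, curvature-seeded
#' region growing, then per accepted region an XY projection, rolling-ball
#' boundary, ordered contour and rasterized binary template.
#'
#' @param cloud a [pod_cloud()] in world mm.
#' @param z_window elevation window `c(zmin, zmax)`; the default keeps
#'   everything above 2 mm (strips the table).
#' @param voxel downsampling voxel size (mm); `NULL` to skip.
#' @param k neighbor count for features and growth.
#' @param angle_thresh,curv_thresh,min_region growth thresholds, see
#'   [growth_params()]. Pipeline defaults are tuned for touching pods on a
#'   table scanned from above (see the package vignette).
#' @param mm_per_pixel template raster resolution.
#' @param ball_radius rolling-ball radius or `"auto"`.
#' @return List with `cloud` (labeled), `regions` (summary data.frame) and
#'   `templates`: per region a list of `contour`, `raster` (see
#'   [rasterize_template()]) and `region_id`.
#' @export
segment_cloud_to_templates <- function(cloud, z_window = c(2, Inf),
                                       voxel = 0.4, k = 30,
                                       angle_thresh = 12, curv_thresh = 0.02,
                                       min_region = 300,
                                       mm_per_pixel = 0.2,
                                       ball_radius = "auto") {
  filtered <- elevation_filter(cloud, z_window[1], z_window[2])
  if (!is.null(voxel)) filtered <- voxel_downsample(filtered, voxel)
  graph <- build_neighbor_graph(filtered, k)
  featured <- estimate_normals_curvature(filtered, graph)
  params <- growth_params(k = k, angle_thresh = angle_thresh,
                          curv_thresh = curv_thresh, min_region = min_region)
  labeled <- region_growing(featured, graph, params)
  regions <- attr(labeled, "regions")
  templates <- lapply(regions$id, function(id) {
    rc <- region_cloud(labeled, id)
    pl <- project_to_plane(rc)
    bb <- rolling_ball_boundary(pl, ball_radius)
    ct <- order_contour(bb, pl)
    rs <- rasterize_template(ct, mm_per_pixel)
    list(region_id = id, contour = ct, raster = rs)
  })
  list(cloud = labeled, regions = regions, templates = templates)
}

#' Match per-pod templates into an adherent 2D image
#'
#' The 2D half of the pipeline: builds a shape model per template, searches
#' the image coarse-to-fine, refines the best candidate poses by the
#' least-squares tangent-distance minimization, resolves conflicts between
#' templates greedily (one image region per template), then extracts and
#' morphologically opens each matched region mask.
#'
#' @param templates template list from [segment_cloud_to_templates()] (each
#'   entry needs a `raster$image`).
#' @param image grayscale scene matrix.
#' @param min_score minimum match score.
#' @param angle_range,scale_range,scale_step search ranges passed to
#'   [build_shape_model()].
#' @param pyramid_levels pyramid depth.
#' @param open_radius structuring-element radius for the final opening (px);
#'   0 disables it.
#' @param refine iterations of [refine_pose()] (0 disables refinement).
#' @return List with `matches` (per template: `pose`, `mask`, `region_id`)
#'   and `masks` (list of final logical masks, one per matched template).
#' @export
match_templates_to_image <- function(templates, image, min_score = 0.45,
                                     angle_range = c(-30, 30),
                                     scale_range = c(0.92, 1.08),
                                     scale_step = 0.04,
                                     pyramid_levels = 4,
                                     open_radius = 2, refine = 5) {
  img <- as.matrix(image)
  edges <- if (refine > 0) edge_image(img) else NULL
  cands <- list()
  for (ti in seq_along(templates)) {
    tp <- templates[[ti]]
    model <- build_shape_model(tp$raster$image, pyramid_levels = pyramid_levels,
                               angle_range = angle_range,
                               scale_range = scale_range,
                               scale_step = scale_step)
    poses <- find_matches(model, img, min_score = min_score, max_matches = 3,
                          max_overlap = 0.5)
    for (p in poses)
      cands[[length(cands) + 1]] <- list(template = ti, model = model, pose = p)
  }
  if (length(cands) == 0) return(list(matches = list(), masks = list()))
  # one detection per template, no two templates on the same spot
  cands <- cands[order(-vapply(cands, function(cd) cd$pose$score, numeric(1)))]
  used_template <- logical(length(templates))
  centers <- NULL
  matches <- list()
  for (cd in cands) {
    if (used_template[cd$template]) next
    ctr <- c(cd$pose$tx, cd$pose$ty)
    if (!is.null(centers) &&
        any(sqrt(colSums((t(centers) - ctr)^2)) < 25)) next
    pose <- cd$pose
    if (refine > 0 && nrow(edges$points) >= 3)
      pose <- refine_pose(cd$model, edges, pose, iterations = refine)
    reg <- extract_region(img, cd$model, pose)
    mask <- reg$mask
    if (open_radius >= 1) mask <- open_mask(mask, open_radius)
    matches[[length(matches) + 1]] <-
      list(template = cd$template, region_id = templates[[cd$template]]$region_id,
           pose = pose, mask = mask)
    used_template[cd$template] <- TRUE
    centers <- rbind(centers, ctr)
  }
  list(matches = matches, masks = lapply(matches, function(m) m$mask))
}

#' Run the full adherent-pod segmentation pipeline on a synthetic scene
#'
#' Convenience wrapper over the whole chain: simulate the stripe scan,
#' reconstruct and splice the cloud, segment it into pods, extract per-pod
#' contour templates, render the top-down scene, match the templates back
#' into the 2D image and score the resulting masks against the generator's
#' ground truth.
#'
#' @param morphologies pod morphologies for [make_scene()].
#' @param seed scene seed.
#' @param mm_per_pixel render/template resolution.
#' @param min_score matcher threshold.
#' @param noise_px stripe jitter for the scan.
#' @param ... further arguments to [segment_cloud_to_templates()].
#' @return List with `scene` (pods), `sim`, `render`, `segmentation`,
#'   `matching`, `score` (a [score_scene()] result) and `iou` (per-pod IoU
#'   vector).
#' @export
run_synthetic_pipeline <- function(morphologies, seed = 1, mm_per_pixel = 0.2,
                                   min_score = 0.45, noise_px = 0, ...) {
  pods <- make_scene(morphologies, seed = seed)
  sim <- simulate_scan(pods, seed = seed, noise_px = noise_px)
  cloud <- assemble_cloud(sim$frames, sim$truth$calib)
  seg <- segment_cloud_to_templates(cloud, ...)
  ren <- render_topdown(pods, mm_per_pixel = mm_per_pixel, seed = seed)
  # templates live in world mm; rebase their rasters onto the render grid
  mt <- match_templates_to_image(seg$templates, ren$image,
                                 min_score = min_score)
  sc <- if (length(mt$masks)) score_scene(mt$masks, ren$masks) else NULL
  iou <- if (is.null(sc)) rep(0, length(pods)) else sc$per_object$IoU
  list(scene = pods, sim = sim, render = ren, segmentation = seg,
       matching = mt, score = sc, iou = iou)
}
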