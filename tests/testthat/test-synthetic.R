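# The ground-truthed scene generator: pod surfaces, the simulated stripe
# scan and the top-down renderer.

test_that("pod surfaces are exact, seeded and morphologically sensible", {
  # degenerate case: equal lobes, no separation, no pinch, no bumps = sphere
  sph <- pod_spec("common", r1 = 9, r2 = 9, sep = 0, waist = 1, bump_amp = 0)
  s1 <- make_pod_surface(sph, samples = 2000, seed = 4)
  ctr <- c(sph$position, sph$axis_height)
  rad <- sqrt(colSums((t(s1$points) - ctr)^2))
  expect_lt(max(abs(rad - 9)), 1e-9)

  # determinism and surface-residual exactness
  s2 <- make_pod_surface(sph, samples = 2000, seed = 4)
  expect_identical(s1$points, s2$points)
  spec <- pod_spec("lollipop")
  sp <- make_pod_surface(spec, samples = 3000, seed = 9)
  expect_lt(max(abs(surface_residual(spec, sp$points)), na.rm = TRUE), 1e-9)

  # wasp waist 0.5: mid-girth to lobe-girth ratio within 2 percent of 0.5
  wasp <- pod_spec("wasp_waist", waist = 0.5, bump_amp = 0)
  u <- seq(0, wasp$length, length.out = 10001)
  rho <- pod_radius(wasp, u)
  ratio <- rho[which.min(abs(u - wasp$length / 2))] / max(rho)
  expect_equal(ratio, 0.5, tolerance = 0.02)

  expect_error(pod_spec("banana"), "unknown morphology")
  expect_error(pod_spec("common", bump_amp = 5), "bump")
  expect_error(make_pod_surface(sph, samples = 100), "samples")
})

test_that("scanning a flat table reproduces its elevation to 1e-6 mm", {
  calib <- synthetic_calibration()
  sim <- simulate_scan(list(), table_z = 4, calib = calib, n_frames = 15)
  cl <- assemble_cloud(sim$frames, calib, intensity_threshold = 1e-6)
  expect_gt(cloud_size(cl), 1000)
  expect_lt(max(abs(cl$points[, 3] - 4)), 1e-6)
  # splice spacing equals speed * frame_interval
  ys <- sort(unique(round(cl$points[, 2], 9)))
  expect_equal(unique(round(diff(ys), 9)),
               calib$speed * calib$frame_interval)
})

test_that("scanning a spherical pod reproduces the analytic surface", {
  calib <- synthetic_calibration()
  sph <- pod_spec("common", r1 = 12, r2 = 12, sep = 0, waist = 1,
                  bump_amp = 0, position = c(0, 80))
  sim <- simulate_scan(list(sph), table_z = 0, calib = calib)
  cl <- assemble_cloud(sim$frames, calib, intensity_threshold = 1e-6)
  expect_equal(cloud_size(cl), cloud_size(sim$truth$cloud))
  pod_pts <- cl$points[sim$truth$cloud$labels == 1, , drop = FALSE]
  res <- abs(surface_residual(sph, pod_pts))
  expect_lt(stats::median(res, na.rm = TRUE), 0.05)
})

test_that("adherent-scene truth labels partition the pod points", {
  pods <- make_scene(c("common", "cocoon"), seed = 3)
  sim <- simulate_scan(pods, seed = 3)
  labs <- sim$truth$cloud$labels
  expect_setequal(unique(labs), c(0L, 1L, 2L))
  expect_gt(sum(labs == 1), 1000)
  expect_gt(sum(labs == 2), 1000)
  # ideal cloud: every point belongs to exactly one pod
  icl <- ideal_adherent_cloud(pods, spacing = 0.5)
  expect_setequal(unique(icl$labels), c(1L, 2L))

  # all-dark scan warns
  expect_warning(simulate_scan(list(), table_z = NA, n_frames = 3), "dark")
})

test_that("the top-down renderer produces exact masks and seeded noise", {
  # empty scene: background plus noise only
  ren0 <- render_topdown(list(), seed = 5)
  expect_equal(mean(ren0$image), 0.12, tolerance = 0.01)
  expect_length(ren0$masks, 0)

  # one pod: a single mask whose area matches the analytic silhouette
  spec <- pod_spec("axe", position = c(0, 0))
  ren1 <- render_topdown(list(spec), mm_per_pixel = 0.2, seed = 5)
  expect_length(ren1$masks, 1)
  area_px <- sum(ren1$masks[[1]]) * 0.2^2
  expect_equal(area_px, silhouette_area(spec), tolerance = 0.03)

  # byte-stable under a fixed seed
  ren2 <- render_topdown(list(spec), mm_per_pixel = 0.2, seed = 5)
  expect_identical(ren1$image, ren2$image)

  # illumination scales mean foreground intensity before clipping
  dim_ren <- render_topdown(list(spec), mm_per_pixel = 0.2, seed = 5,
                            illumination = 0.5)
  fg <- ren1$masks[[1]]
  expect_equal(mean(dim_ren$image[fg]) / mean(ren1$image[fg]), 0.5,
               tolerance = 0.03)

  # masks of adherent pods are disjoint
  pods <- make_scene(c("common", "wasp_waist"), seed = 8)
  renp <- render_topdown(pods, seed = 8)
  expect_equal(sum(renp$masks[[1]] & renp$masks[[2]]), 0)

  # deep interpenetration is rejected
  a <- pod_spec("common", position = c(0, 0))
  b <- pod_spec("common", position = c(5, 0))
  expect_error(render_topdown(list(a, b)), "interpenetrate")
})

test_that("scan generators are deterministic under a fixed seed", {
  pods <- make_scene(c("axe", "lollipop"), seed = 21)
  pods2 <- make_scene(c("axe", "lollipop"), seed = 21)
  expect_identical(pods, pods2)
  s1 <- simulate_scan(pods, n_frames = 30, noise_px = 0.3, seed = 6)
  s2 <- simulate_scan(pods, n_frames = 30, noise_px = 0.3, seed = 6)
  expect_identical(s1$frames[[15]]$image, s2$frames[[15]]$image)
  # noise really perturbs the stripe
  s3 <- simulate_scan(pods, n_frames = 30, noise_px = 0.3, seed = 7)
  expect_false(identical(s1$frames[[15]]$image, s3$frames[[15]]$image))
})
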