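# Stripe centerline extraction, light-plane triangulation, the extrinsic
# world transform and stripe-stack splicing.

published_intrinsics <- camera_intrinsics(1027, 1027, 1224, 972)
published_plane <- light_plane(0.000022, -0.000003, 0.001877, 1)
published_R <- matrix(c(-0.7651, -0.6438, -0.0116,
                    0.6439, -0.7651, -0.0003,
                    -0.0087, -0.0077, 0.9999), 3, 3, byrow = TRUE)
published_T <- c(30.3430, 12.0417, 533.1570)

test_that("centerline is the per-column intensity-weighted centroid", {
  img <- matrix(0, 40, 30)
  img[18, 5] <- 120                      # single bright pixel, row 17 0-based
  img[11, 10] <- 80; img[13, 10] <- 80   # symmetric pair around row 11
  cl <- extract_stripe_centerline(stripe_frame(img, 0), 30)
  expect_equal(unname(cl[cl[, "u"] == 4, "v"]), 17)
  expect_equal(unname(cl[cl[, "u"] == 9, "v"]), 11)
  expect_equal(nrow(cl), 2)   # one entry per lit column only

  # discrete Gaussian profile centered at 20.3: centroid within 0.1
  rows <- 0:39
  prof <- 100 * exp(-(rows - 20.3)^2 / (2 * 1.5^2))
  img2 <- matrix(0, 40, 3)
  img2[, 2] <- prof
  cl2 <- extract_stripe_centerline(img2, 5)
  expect_equal(unname(cl2[cl2[, "u"] == 1, "v"]), 20.3, tolerance = 0.1 / 20.3)
  # direct centroid oracle on the same thresholded profile
  sel <- prof > 5
  expect_equal(unname(cl2[cl2[, "u"] == 1, "v"]),
               sum(rows[sel] * prof[sel]) / sum(prof[sel]))
})

test_that("centerline edge cases behave as specified", {
  expect_error(extract_stripe_centerline(matrix(numeric(0), 0, 0), 1), "empty")
  res <- extract_stripe_centerline(matrix(1, 5, 5), 10)  # threshold above max
  expect_equal(nrow(res), 0)
  expect_error(stripe_frame(matrix(1, 2, 2), -1), "timestamp")
})

test_that("backprojection solves the ray/light-plane intersection exactly", {
  intr <- camera_intrinsics(800, 820, 320, 240)
  p <- backproject_to_plane(c(320, 240), intr, light_plane(0, 0, 1, -500))
  expect_equal(unname(p), matrix(c(0, 0, 500), 1), tolerance = 1e-12)

  # a published rig calibration: principal-ray depth is -1/c (negative sign convention)
  pp <- backproject_to_plane(c(1224, 972), published_intrinsics, published_plane)
  expect_equal(unname(pp[1, 3]), -1 / 0.001877, tolerance = 1e-9)
  # independent oracle: solve the linear system of pinhole rows + plane row
  px <- c(1502.3, 700.9)
  A <- rbind(c(1027, 0, 1224 - px[1]),
             c(0, 1027, 972 - px[2]),
             c(0.000022, -0.000003, 0.001877))
  oracle <- solve(A, c(0, 0, -1))
  expect_equal(unname(backproject_to_plane(px, published_intrinsics, published_plane)[1, ]),
               unname(oracle), tolerance = 1e-9)
})

test_that("triangulation round trip and plane membership hold for random inputs", {
  set.seed(11)
  for (rep in 1:25) {
    intr <- camera_intrinsics(runif(1, 400, 2000), runif(1, 400, 2000),
                              runif(1, 200, 1400), runif(1, 200, 1000))
    pl <- light_plane(runif(1, -0.01, 0.01), runif(1, -0.01, 0.01),
                      runif(1, 0.5, 2) * sample(c(-1, 1), 1), runif(1, 100, 900))
    px <- cbind(runif(40, 0, 2400), runif(40, 0, 2000))
    cam <- backproject_to_plane(px, intr, pl)
    expect_lt(max(abs(project_pixels(cam, intr) - px)), 1e-9)
    resid <- pl$a * cam[, 1] + pl$b * cam[, 2] + pl$c * cam[, 3] + pl$d
    expect_lt(max(abs(resid)), 1e-9)
  }
  expect_error(backproject_to_plane(c(320, 240),
                                    camera_intrinsics(800, 800, 320, 240),
                                    light_plane(1, 0, 0, 5)),
               "parallel")
})

test_that("world transform inverts the extrinsic map", {
  I3 <- extrinsics(diag(3), c(0, 0, 0))
  p <- matrix(c(1.5, -2, 7), 1)
  expect_equal(unname(camera_to_world(p, I3)), unname(p))

  ex <- suppressWarnings(extrinsics(published_R, published_T))
  expect_equal(unname(camera_to_world(matrix(published_T, 1), ex)),
               matrix(0, 1, 3), tolerance = 1e-9)

  # exact agreement with the numeric 4x4 inverse for proper rotations
  set.seed(21)
  for (rep in 1:10) {
    ang <- runif(3, -pi, pi)
    Rx <- matrix(c(1, 0, 0, 0, cos(ang[1]), sin(ang[1]),
                   0, -sin(ang[1]), cos(ang[1])), 3, 3)
    Rz <- matrix(c(cos(ang[3]), sin(ang[3]), 0,
                   -sin(ang[3]), cos(ang[3]), 0, 0, 0, 1), 3, 3)
    R <- Rz %*% Rx
    Tv <- runif(3, -100, 100)
    ex2 <- extrinsics(R, Tv)
    M <- rbind(cbind(R, Tv), c(0, 0, 0, 1))
    pt <- runif(3, -50, 50)
    expect_equal(as.numeric(camera_to_world(pt, ex2)),
                 (solve(M) %*% c(pt, 1))[1:3], tolerance = 1e-9)
  }

  # the printed rotation is orthonormal only to ~1e-3: warn, don't fail,
  # and stay close to the generic numeric inverse
  expect_warning(extrinsics(published_R, published_T), "orthonormal")
  M <- rbind(cbind(published_R, published_T), c(0, 0, 0, 1))
  num <- (solve(M) %*% c(0, 0, 0, 1))[1:3]
  expect_equal(as.numeric(camera_to_world(c(0, 0, 0), ex)), num,
               tolerance = 2e-4)
})

test_that("splicing offsets frames by d = v t along the guide axis", {
  img <- matrix(0, 20, 10)
  img[8, 3:7] <- 100
  intr <- camera_intrinsics(500, 500, 5, 10)
  pl <- light_plane(0, 0, 1, -400)
  ex <- extrinsics(diag(3), c(0, 0, 0))

  calib <- calibration_set(intr, pl, ex, speed = 1, frame_interval = 1)
  frames <- list(stripe_frame(img, 0, 1), stripe_frame(img, 2, 2))
  cl <- assemble_cloud(frames, calib, 30)
  n <- cloud_size(cl) / 2
  first <- cl$points[seq_len(n), ]
  second <- cl$points[n + seq_len(n), ]
  expect_equal(second - first,
               matrix(rep(c(0, 2, 0), each = n), ncol = 3))  # exactly 2 mm
  expect_equal(unique(cl$frame_ids), c(1L, 2L))

  # speed 0.1 mm/s at t = 10 s -> 1 mm offset
  calib01 <- calibration_set(intr, pl, ex, speed = 0.1, frame_interval = 1)
  fr01 <- list(stripe_frame(img, 0, 1), stripe_frame(img, 10, 2))
  cl01 <- assemble_cloud(fr01, calib01, 30)
  expect_equal(unique(cl01$points[n + seq_len(n), 2] - cl01$points[seq_len(n), 2]), 1)

  # v = 0: all frames superimpose
  calib0 <- calibration_set(intr, pl, ex, speed = 0, frame_interval = 1)
  cl0 <- assemble_cloud(frames, calib0, 30)
  expect_equal(cl0$points[seq_len(n), ], cl0$points[n + seq_len(n), ])

  # doubling the frame interval doubles inter-frame offsets exactly
  fr_a <- list(stripe_frame(img, 0, 1), stripe_frame(img, 1, 2))
  fr_b <- list(stripe_frame(img, 0, 1), stripe_frame(img, 2, 2))
  off <- function(fr) {
    cc <- assemble_cloud(fr, calib, 30)
    cc$points[n + 1, 2] - cc$points[1, 2]
  }
  expect_equal(off(fr_b), 2 * off(fr_a))

  expect_warning(assemble_cloud(list(stripe_frame(matrix(0, 5, 5), 0, 1)),
                                calib, 30), "empty")
  expect_error(assemble_cloud(list(stripe_frame(img, 3, 1),
                                   stripe_frame(img, 1, 2)), calib),
               "increasing")
})

test_that("calibration files round-trip through YAML and JSON", {
  calib <- calibration_set(published_intrinsics, published_plane,
                           suppressWarnings(extrinsics(published_R, published_T)),
                           speed = 0.1, frame_interval = 1)
  for (ext in c("yaml", "json")) {
    f <- tempfile(fileext = paste0(".", ext))
    write_calibration(calib, f)
    back <- suppressWarnings(read_calibration(f))
    expect_equal(back$intrinsics, calib$intrinsics)
    expect_equal(back$plane, calib$plane)
    expect_equal(back$extrinsics$R, calib$extrinsics$R, tolerance = 1e-8)
    expect_equal(back$speed, 0.1)
    unlink(f)
  }
})

test_that("point clouds round-trip through ASCII PLY and CSV", {
  set.seed(5)
  pts <- matrix(runif(60, -10, 10), 20, 3)
  nrm <- matrix(rnorm(60), 20, 3)
  nrm <- nrm / sqrt(rowSums(nrm^2))
  cl <- pod_cloud(pts, normals = nrm, curvatures = runif(20, 0, 1 / 3),
                  labels = sample(c(-1L, 0L, 1L), 20, TRUE))
  for (rw in list(c(write_cloud_ply, read_cloud_ply),
                  c(write_cloud_csv, read_cloud_csv))) {
    f <- tempfile(fileext = ".dat")
    rw[[1]](cl, f)
    back <- rw[[2]](f)
    expect_equal(back$points, cl$points, tolerance = 1e-6)
    expect_equal(back$labels, cl$labels)
    expect_lt(max(abs(back$normals - cl$normals)), 1e-6)
    unlink(f)
  }
})

test_that("frame directories round-trip through PNG", {
  dir <- tempfile(); dir.create(dir)
  img <- matrix(0, 16, 12)
  img[7, 4:9] <- 200
  for (i in 0:2)
    png::writePNG(img / 255, file.path(dir, sprintf("frame_%05d.png", i)))
  frames <- read_frames(dir, frame_interval = 0.5)
  expect_length(frames, 3)
  expect_equal(frames[[2]]$timestamp, 0.5)
  expect_equal(frames[[3]]$image, img, tolerance = 1e-6)
  unlink(dir, recursive = TRUE)
})
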