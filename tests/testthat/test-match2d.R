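# Shape-model construction, pyramid matching, least-squares pose refinement,
# region extraction and morphological opening.

test_that("shape models encode the template outline with outward normals", {
  img <- matrix(0, 40, 40)
  img[11:30, 11] <- 1; img[11:30, 30] <- 1
  img[11, 11:30] <- 1; img[30, 11:30] <- 1    # hollow 20x20 square
  model <- build_shape_model(img, pyramid_levels = 1, max_points = 200)
  expect_length(model$levels, 1)
  pts <- sweep(model$levels[[1]]$points, 2, -model$origin)  # absolute coords
  nrm <- model$levels[[1]]$normals
  # points on the square; normals axis-aligned outward (away from center)
  ctr <- colMeans(pts)
  away <- rowSums(nrm * sweep(pts, 2, ctr))
  edge_pts <- abs(abs(pts[, 1] - ctr[1]) - 10) < 1.5 |
    abs(abs(pts[, 2] - ctr[2]) - 10) < 1.5
  expect_true(mean(edge_pts) > 0.95)
  expect_true(mean(away > 0) > 0.9)
  expect_lt(max(abs(sqrt(rowSums(nrm^2)) - 1)), 1e-8)

  # multi-level pyramid: coarser levels have fewer points, all levels >= 8
  big <- ellipse_image(120, 160, 80, 60, 45, 25)
  m2 <- build_shape_model(big, pyramid_levels = 4)
  sizes <- vapply(m2$levels, function(l) nrow(l$points), integer(1))
  expect_true(all(diff(sizes) < 0))
  expect_true(all(sizes >= 8))

  # area filter must leave exactly one component
  two <- matrix(0, 30, 60)
  two[10:20, 10:20] <- 1; two[10:20, 40:50] <- 1
  expect_error(build_shape_model(two, area_range = c(1, Inf)), "2 component")
  expect_error(build_shape_model(matrix(0, 10, 10)), "no foreground")
})

test_that("ellipse model normals agree with the analytic outward normal", {
  img <- ellipse_image(260, 320, 160, 130, 110, 70)
  model <- build_shape_model(img, pyramid_levels = 1)
  pts <- sweep(model$levels[[1]]$points, 2, -model$origin)
  nrm <- model$levels[[1]]$normals
  # analytic outward normal of (x/a)^2 + (y/b)^2 = 1 at the contour points
  dx <- pts[, 1] - 160; dy <- pts[, 2] - 130
  an <- cbind(dx / 110^2, dy / 70^2)
  an <- an / sqrt(rowSums(an^2))
  ang <- acos(pmin(1, abs(rowSums(an * nrm)))) * 180 / pi
  expect_lt(unname(stats::quantile(ang, 0.95)), 5)
  # the contour exceeds the budget, so the count hits the subsampling target
  expect_equal(nrow(pts), 512, tolerance = 0.1)
})

test_that("pyramid search finds the template and rejects noise", {
  img <- ellipse_image(120, 160, 80, 60, 45, 25)
  model <- build_shape_model(img, pyramid_levels = 3, angle_step = 2)
  m <- find_matches(model, img, min_score = 0.5, max_matches = 3)
  expect_gte(length(m), 1)
  best <- m[[1]]
  expect_gte(best$score, 0.95)
  expect_lte(abs(best$tx - 80), 1)
  expect_lte(abs(best$ty - 60), 1)
  # the ellipse is 180-degree symmetric; compare rotation modulo pi
  expect_lte(abs(sin(best$theta)), sin(1 * pi / 180))
  expect_lte(abs(best$scale - 1), 0.02)

  # pure noise: nothing reaches a high score
  set.seed(91)
  noise <- matrix(runif(120 * 160), 120, 160)
  expect_length(find_matches(model, noise, min_score = 0.8), 0)

  # integer translation of the target translates the pose exactly
  i1 <- ellipse_image(200, 240, 100, 80, 45, 25)
  i2 <- ellipse_image(200, 240, 108, 88, 45, 25)
  p1 <- find_matches(model, i1, min_score = 0.5, max_matches = 1)[[1]]
  p2 <- find_matches(model, i2, min_score = 0.5, max_matches = 1)[[1]]
  expect_equal(unname(p2$tx - p1$tx), 8)
  expect_equal(unname(p2$ty - p1$ty), 8)

  expect_error(find_matches(model, i1, min_score = 0), "min_score")
})

test_that("both pods of a rendered adherent scene are recovered", {
  pods <- make_scene(c("common", "axe"), seed = 31)
  ren <- render_topdown(pods, mm_per_pixel = 0.25, seed = 31)
  found <- list()
  for (i in seq_along(pods)) {
    tmpl <- ifelse(ren$masks[[i]], 1, 0)
    model <- build_shape_model(tmpl, pyramid_levels = 3,
                               angle_range = c(-20, 20),
                               scale_range = c(0.95, 1.05), scale_step = 0.05)
    m <- find_matches(model, ren$image, min_score = 0.4, max_matches = 1)
    expect_gte(length(m), 1)
    # truth pose: the mask centroid (the model origin is the mask contour
    # centroid, built from the mask itself)
    truth <- unname(colMeans(which(ren$masks[[i]], arr.ind = TRUE))[c(2, 1)])
    expect_lte(abs(m[[1]]$tx - truth[1]), 2)
    expect_lte(abs(m[[1]]$ty - truth[2]), 2)
    expect_lte(abs(m[[1]]$theta) * 180 / pi, 2)
    expect_lte(abs(m[[1]]$scale - 1), 0.03)
    found[[i]] <- m[[1]]
  }
  expect_gt(abs(found[[1]]$tx - found[[2]]$tx), 20)  # two distinct pods
})

test_that("least-squares refinement recovers known pose perturbations", {
  img <- ellipse_image(120, 160, 80, 60, 45, 25)
  model <- build_shape_model(img, pyramid_levels = 1)
  init <- pod_pose(0, 80, 60, 1, 0.9)

  # exact overlap: zero update
  e0 <- edge_image(img)
  r0 <- refine_pose(model, e0, init)
  expect_lt(abs(r0$theta), 1e-6)
  expect_lt(abs(r0$tx - 80) + abs(r0$ty - 60), 1e-6)

  # known shifts up to 3 px recovered within 0.1 px
  for (dx in c(1, 2, 3)) {
    es <- edge_image(ellipse_image(120, 160, 80 + dx, 60, 45, 25))
    rs <- refine_pose(model, es, init)
    expect_lt(abs(rs$tx - (80 + dx)), 0.1)
    expect_lt(abs(rs$ty - 60), 0.1)
    expect_lt(abs(rs$theta) * 180 / pi, 0.2)
    # residual trace is non-increasing at every iteration
    expect_true(all(diff(attr(rs, "residual_trace")) <= 1e-12))
  }

  # rotations up to 3 degrees recovered within 0.3 degrees
  for (deg in c(1.5, 3)) {
    er <- edge_image(ellipse_image(120, 160, 80, 60, 45, 25,
                                   theta = deg * pi / 180))
    rr <- refine_pose(model, er, init)
    expect_lt(abs(rr$theta * 180 / pi - deg), 0.3)
    expect_true(all(diff(attr(rr, "residual_trace")) <= 1e-12))
  }

  # degenerate: far-away edges give no correspondences, init returned flagged
  far <- edge_image(ellipse_image(400, 400, 350, 350, 20, 12))
  rf <- refine_pose(model, far, init)
  expect_true(attr(rf, "degenerate"))
  expect_equal(rf$tx, init$tx)
})

test_that("region extraction fills the transformed contour", {
  img <- matrix(0, 60, 60)
  sq <- matrix(0, 60, 60); sq[21:40, 21:40] <- 1
  model <- build_shape_model(sq, pyramid_levels = 1)
  reg <- extract_region(img, model, pod_pose(0, model$origin[1],
                                             model$origin[2], 1, 1))
  expect_equal(sum(reg$mask), 400, tolerance = 0.1)
  expect_true(all(which(reg$mask, arr.ind = TRUE)[, 1] %in% 20:41))

  # mask area scales with pose scale^2 (within rasterization error)
  reg2 <- extract_region(img, model, pod_pose(0, 30, 30, 1.5, 1))
  expect_equal(sum(reg2$mask) / sum(reg$mask), 1.5^2, tolerance = 0.1)

  # partially outside: clipped with a warning
  expect_warning(extract_region(img, model, pod_pose(0, 3, 30, 1, 1)),
                 "clipped")
})

test_that("opening is anti-extensive and idempotent", {
  m <- matrix(FALSE, 30, 30)
  m[15, 15] <- TRUE
  expect_equal(sum(open_mask(m, 1)), 0)      # isolated pixel removed

  solid <- matrix(FALSE, 60, 60); solid[6:55, 6:55] <- TRUE
  op_solid <- open_mask(solid, 2)
  # bulk shape preserved: a disc cannot reproduce sharp corners exactly, so
  # allow at most the 4 corner pixels to round off
  expect_true(all(op_solid <= solid))
  expect_lte(sum(solid & !op_solid), 4)
  # a disc-shaped mask is exactly invariant under disc opening
  disc <- t(EBImage::imageData(EBImage::makeBrush(21, "disc"))) > 0
  expect_equal(open_mask(disc, 2) | FALSE, disc | FALSE)

  set.seed(17)
  for (rep in 1:3) {
    rmask <- matrix(runif(900) > 0.6, 30, 30)
    op <- open_mask(rmask, 1)
    expect_true(all(op <= rmask))            # anti-extensive
    expect_equal(open_mask(op, 1), op)       # idempotent
  }
  expect_error(open_mask(m, 0), "se_radius")
})
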