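# XY projection, rolling-ball boundary extraction, contour ordering and
# template rasterization.

test_that("projection keeps XY, drops Z and preserves indices", {
  cl <- pod_cloud(rbind(c(1, 2, 5), c(3, 4, 9)))
  pl <- project_to_plane(cl)
  expect_equal(unname(pl$points2d), rbind(c(1, 2), c(3, 4)))
  expect_equal(pl$source_indices, 1:2)
  # idempotent in XY
  cl2 <- pod_cloud(cbind(pl$points2d, 0))
  expect_equal(project_to_plane(cl2)$points2d, pl$points2d)
  expect_error(project_to_plane(pod_cloud(matrix(numeric(0), 0, 3))), "empty")

  # projected extent of a sampled pod matches its silhouette extents
  spec <- pod_spec("common", bump_amp = 0, position = c(0, 0))
  surf <- make_pod_surface(spec, samples = 20000, seed = 3)
  ext <- unname(apply(surf$points[, 1:2], 2, function(v) diff(range(v))))
  expect_equal(ext[1], spec$length, tolerance = 0.01)
  expect_equal(ext[2], 2 * spec$axis_height, tolerance = 0.01)
})

test_that("rolling ball handles the canonical small configurations", {
  # equilateral triangle with r >= circumradius: all points, all edges
  s <- 2
  tri <- rbind(c(0, 0), c(s, 0), c(s / 2, s * sqrt(3) / 2))
  bb <- rolling_ball_boundary(tri, radius = s / sqrt(3) + 0.01)
  expect_equal(bb$boundary, 1:3)
  expect_equal(nrow(bb$edges), 3)

  # unit square, r = 1: oracle fixes the exact edge set (incl. diagonals)
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  bb2 <- rolling_ball_boundary(sq, radius = 1)
  oracle <- naive_rollball(sq, 1)
  expect_equal(unname(bb2$edges), unname(oracle[order(oracle[, 1], oracle[, 2]), ]))
  expect_equal(bb2$boundary, 1:4)

  # duplicate points are removed with a warning
  expect_warning(rolling_ball_boundary(rbind(tri, c(0, 0)), radius = 2),
                 "duplicate")
  expect_error(rolling_ball_boundary(tri[1:2, ], 1), "3 points")
  expect_error(rolling_ball_boundary(tri, -1), "radius")
})

test_that("rolling-ball edges equal the exhaustive oracle on random sets", {
  set.seed(71)
  for (rep in 1:6) {
    M <- sample(30:90, 1)
    P <- matrix(runif(2 * M, 0, 10), M, 2)
    r <- runif(1, 0.8, 3)
    fast <- rolling_ball_boundary(P, r)
    oracle <- naive_rollball(P, r)
    if (nrow(oracle)) oracle <- oracle[order(oracle[, 1], oracle[, 2]), , drop = FALSE]
    expect_equal(unname(fast$edges), unname(oracle))
  }
})

test_that("hull subset, scale equivariance and radius monotonicity hold", {
  set.seed(72)
  for (rep in 1:5) {
    P <- matrix(runif(160, 0, 10), 80, 2)
    hull <- chull(P)
    hp <- P[c(hull, hull[1]), ]
    longest <- max(sqrt(rowSums(diff(hp)^2)))
    r <- longest / 2 + 0.5    # r >= half the longest hull edge
    bb <- rolling_ball_boundary(P, r)
    expect_true(all(hull %in% bb$boundary))

    # scaling coordinates and radius together preserves the index set
    bb2 <- rolling_ball_boundary(P * 3.7, r * 3.7)
    expect_equal(bb2$boundary, bb$boundary)
    expect_equal(bb2$edges, bb$edges)
  }

  # on convex-position points, growing r never removes a hull vertex
  th <- seq(0, 2 * pi, length.out = 13)[-13]
  conv <- cbind(cos(th) * (3 + 0.3 * sin(3 * th)), sin(th) * 3)
  prev <- NULL
  for (r in c(1, 2, 4, 8)) {
    bset <- rolling_ball_boundary(conv, r)$boundary
    if (!is.null(prev)) expect_true(all(prev %in% bset))
    prev <- intersect(chull(conv), bset)
  }
})

test_that("contour ordering produces closed CCW polygons", {
  tri <- rbind(c(0, 0), c(2, 0), c(1, 1.5))
  bb <- rolling_ball_boundary(tri, radius = 2)
  ct <- order_contour(bb, tri)
  expect_true(ct$is_closed)
  expect_equal(nrow(ct$vertices), 4)              # closed: first == last
  expect_equal(ct$vertices[1, ], ct$vertices[4, ])
  expect_gt(polygon_area(ct$vertices), 0)         # CCW

  # square with both diagonals present: the outer loop wins
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  edges <- rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 1), c(1, 3), c(2, 4))
  ct2 <- order_contour(edges, sq)
  expect_equal(abs(polygon_area(ct2$vertices)), 1, tolerance = 1e-12)

  expect_error(order_contour(edges[1:2, ], sq), "3 boundary edges")
})

test_that("a sampled ellipse contour recovers the analytic area", {
  set.seed(73)
  a <- 10; b <- 6
  th <- runif(4000, 0, 2 * pi); rr <- sqrt(runif(4000))
  ring <- seq(0, 2 * pi, length.out = 600)[-600]
  P <- rbind(cbind(a * rr * cos(th), b * rr * sin(th)),
             cbind(a * cos(ring), b * sin(ring)))
  bb <- rolling_ball_boundary(P, radius = 3 * rollball_radius(P) / 3)
  ct <- order_contour(bb, P)
  expect_equal(abs(polygon_area(ct$vertices)), pi * a * b, tolerance = 0.03)
})

test_that("rasterization follows the cell-grid contract", {
  # 10 mm axis-aligned square at 1 mm/px with pad 2: 14 x 14, 10 x 10 outline
  sq <- rbind(c(0, 0), c(10, 0), c(10, 10), c(0, 10), c(0, 0))
  rt <- rasterize_template(sq, 1, pad = 2)
  expect_equal(dim(rt$image), c(14, 14))
  on <- which(rt$image == 1, arr.ind = TRUE)
  expect_equal(range(on[, 1]), c(3, 12))   # rows 3..12 = 10 px
  expect_equal(range(on[, 2]), c(3, 12))
  interior <- rt$image[5:10, 5:10]
  expect_equal(sum(interior), 0)           # hollow

  # halving the resolution halves the bounding box (+/- 1 px)
  rt2 <- rasterize_template(sq, 2, pad = 2)
  expect_lte(abs(dim(rt2$image)[1] - (dim(rt$image)[1] - 4) / 2 - 4), 1)

  expect_error(rasterize_template(rbind(c(0, 0), c(1, 0), c(2, 0)), 1),
               "degenerate")
  expect_error(rasterize_template(sq, 0), "mm_per_pixel")
})

test_that("rasterized contours re-vectorize close to the original", {
  th <- seq(0, 2 * pi, length.out = 200)[-200]
  ell <- cbind(8 * cos(th), 5 * sin(th))
  mpp <- 0.25
  rt <- rasterize_template(rbind(ell, ell[1, ]), mpp, pad = 2)
  on <- which(rt$image == 1, arr.ind = TRUE)  # (row, col)
  mm <- cbind(rt$origin[1] + (on[, 2] - 1) * mpp,
              rt$origin[2] + (on[, 1] - 1) * mpp)
  expect_lt(hausdorff2(mm, ell) / mpp, 1.5)
})
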