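#' Project a cloud onto the table plane
#'
#' Orthographic projection onto the world XY plane (the camera looks straight
#' down in this rig, so the XY footprint is the object silhouette).
#'
#' @param cloud a non-empty [pod_cloud()].
#' @return An object of class `planar_points`: `points2d` (M x 2, mm) and
#'   `source_indices` mapping each 2D point back to its cloud point.
#' @export
project_to_plane <- function(cloud) {
  if (cloud_size(cloud) == 0) stop("cloud is empty")
  structure(list(points2d = cloud$points[, 1:2, drop = FALSE],
                 source_indices = seq_len(cloud_size(cloud))),
            class = "planar_points")
}

#' Default rolling-ball radius
#'
#' Three times the median nearest-neighbor spacing of the projected points:
#' large enough to bridge sampling gaps, small enough to follow concavities.
#'
#' @param pts a `planar_points` object (or M x 2 matrix).
#' @return radius in mm.
#' @export
rollball_radius <- function(pts) {
  p <- planar_matrix(pts)
  nn <- knn_grid(p, 1L)
  3 * stats::median(nn$dist[, 1])
}

planar_matrix <- function(pts) {
  p <- if (inherits(pts, "planar_points")) pts$points2d else as.matrix(pts)
  storage.mode(p) <- "double"
  stopifnot(ncol(p) == 2)
  p
}

#' Rolling-ball boundary extraction
#'
#' A point pair `(A, B)` with `|AB| <= 2r` forms a boundary edge when at
#' least one of the two radius-`r` circles passing through both points
#' contains no other point strictly inside (strictly means closer than
#' `r - eps` to the center, with `eps = 1e-9 * r`, so points lying exactly on
#' a circle never block an edge). Boundary points are the endpoints of
#' boundary edges. Chords of length exactly `2r` are handled by the same
#' formula (the two centers coincide).
#'
#' @param pts a `planar_points` object or M x 2 matrix, M >= 3. Duplicate
#'   coordinates are deduplicated with a warning before traversal.
#' @param radius ball radius in mm (> 0), or `"auto"` for
#'   [rollball_radius()].
#' @return List with `boundary` (sorted indices into the input points),
#'   `edges` (E x 2 index matrix, first index < second) and `radius`.
#' @export
rolling_ball_boundary <- function(pts, radius = "auto") {
  p <- planar_matrix(pts)
  if (nrow(p) < 3) stop("need at least 3 points")
  if (identical(radius, "auto")) radius <- rollball_radius(p)
  if (!(radius > 0)) stop("radius must be positive")
  key <- paste(p[, 1], p[, 2])
  first <- match(key, key)
  dup <- first != seq_len(nrow(p))
  if (any(dup)) {
    warning(sprintf("%d duplicate point(s) removed before boundary traversal",
                    sum(dup)))
    keep <- which(!dup)
    p <- p[keep, , drop = FALSE]
  } else keep <- seq_len(nrow(p))
  if (nrow(p) < 3) stop("fewer than 3 distinct points")
  E <- rollball_edges_cpp(p, radius, 1e-9 * radius)
  edges <- cbind(keep[E[, 1]], keep[E[, 2]])
  if (nrow(edges)) {
    swap <- edges[, 1] > edges[, 2]
    edges[swap, ] <- edges[swap, 2:1]
    edges <- edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
  }
  list(boundary = sort(unique(as.integer(edges))), edges = edges,
       radius = radius)
}

#' Order boundary edges into a closed contour polygon
#'
#' Traces the outer face of the boundary-edge graph: starting from the
#' bottom-most boundary vertex, the walk repeatedly takes the edge making
#' the largest counter-clockwise angle from the direction it arrived on
#' (leftmost-turn rule, reversing only at dead ends), which follows the
#' outermost closed loop of the graph and ignores interior chords and
#' spurious short loops. The result is normalized to counter-clockwise
#' orientation with consecutive duplicate vertices removed.
#'
#' @param edges boundary edge list (E x 2), e.g. from
#'   [rolling_ball_boundary()].
#' @param pts the `planar_points` (or M x 2 matrix) the edges index into.
#' @return An object of class `pod_contour`: `vertices` (closed CCW polygon,
#'   first row repeated last), `is_closed`, `radius_used` (NA when unknown).
#' @export
order_contour <- function(edges, pts) {
  p <- planar_matrix(pts)
  if (is.list(edges) && !is.null(edges$edges)) {
    radius <- edges$radius
    edges <- edges$edges
  } else radius <- NA_real_
  edges <- as.matrix(edges)
  if (nrow(edges) < 3) stop("need at least 3 boundary edges")

  nodes <- sort(unique(as.integer(edges)))
  adj <- vector("list", max(nodes))
  for (e in seq_len(nrow(edges))) {
    a <- edges[e, 1]; b <- edges[e, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }

  start <- nodes[order(p[nodes, 2], p[nodes, 1])][1]
  prev_dir <- pi            # virtual arrival pointing -x: first pick is the
  path <- start             # most clockwise upward edge, so the walk runs CCW
  cur <- start
  prev <- NA_integer_
  max_steps <- 2L * nrow(edges) + 2L
  for (step in seq_len(max_steps)) {
    cand <- adj[[cur]]
    dirs <- atan2(p[cand, 2] - p[cur, 2], p[cand, 1] - p[cur, 1])
    rel <- (dirs - (prev_dir + pi)) %% (2 * pi)
    is_back <- !is.na(prev) & cand == prev &
      (rel < 1e-9 | rel > 2 * pi - 1e-9)
    rel[is_back] <- -Inf    # reverse only when nothing else is available
    if (all(rel == -Inf)) rel[is_back] <- 2 * pi
    nxt <- cand[order(-rel, cand)][1]
    if (nxt == start && step > 1) break
    if (step == max_steps)
      stop(sprintf(paste0("no closed outer loop found in the boundary-edge ",
                          "graph (%d edges over %d nodes)"),
                   nrow(edges), length(nodes)))
    path <- c(path, nxt)
    prev_dir <- atan2(p[nxt, 2] - p[cur, 2], p[nxt, 1] - p[cur, 1])
    prev <- cur
    cur <- nxt
  }
  if (length(path) < 3)
    stop("no closed outer loop found in the boundary-edge graph")

  verts <- p[path, , drop = FALSE]
  dup <- c(FALSE, rowSums(abs(diff(verts))) == 0)
  verts <- verts[!dup, , drop = FALSE]
  if (polygon_area(verts) < 0) verts <- verts[rev(seq_len(nrow(verts))), , drop = FALSE]
  verts <- rbind(verts, verts[1, ])
  structure(list(vertices = verts, is_closed = TRUE, radius_used = radius,
                 source_path = path),
            class = "pod_contour")
}

#' Signed polygon area (shoelace)
#' @param verts polygon vertex matrix (closed or open).
#' @return signed area; positive for counter-clockwise.
#' @export
polygon_area <- function(verts) {
  v <- as.matrix(verts)
  if (nrow(v) > 1 && all(v[1, ] == v[nrow(v), ])) v <- v[-nrow(v), , drop = FALSE]
  x <- v[, 1]; y <- v[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

#' @export
print.pod_contour <- function(x, ...) {
  cat(sprintf("pod_contour: %d vertices, area %.2f mm^2, ball radius %s\n",
              nrow(x$vertices) - 1, abs(polygon_area(x$vertices)),
              if (is.na(x$radius_used)) "unknown"
              else sprintf("%.3f mm", x$radius_used)))
  invisible(x)
}

#' Rasterize a contour into a binary template image
#'
#' Draws the closed polygon as a 1-pixel-wide digital contour (Bresenham
#' lines between consecutive vertices) on a padded pixel grid. Pixels are
#' cells of size `mm_per_pixel`; pixel `(row, col)` (0-based) covers mm
#' coordinates `origin + (col, row) * mm_per_pixel` at its center, with image
#' rows increasing along +Y.
#'
#' @param contour a [order_contour()] result (or vertex matrix in mm).
#' @param mm_per_pixel pixel size (mm, > 0).
#' @param pad margin in pixels around the contour bounding box.
#' @return List with `image` (0/1 matrix), `origin` (mm of the center of
#'   pixel (0,0)), `mm_per_pixel`.
#' @export
rasterize_template <- function(contour, mm_per_pixel, pad = 2) {
  if (!(mm_per_pixel > 0)) stop("mm_per_pixel must be positive")
  verts <- if (inherits(contour, "pod_contour")) contour$vertices
           else as.matrix(contour)
  if (nrow(verts) < 3 || abs(polygon_area(verts)) < (mm_per_pixel^2) / 4)
    stop("degenerate (zero-area) contour")
  if (any(verts[1, ] != verts[nrow(verts), ])) verts <- rbind(verts, verts[1, ])
  lo <- apply(verts, 2, min)
  hi <- apply(verts, 2, max)
  inner <- pmax(ceiling((hi - lo) / mm_per_pixel), 1)
  nx <- inner[1] + 2 * pad
  ny <- inner[2] + 2 * pad
  to_px <- function(v) {
    cx <- pmin(floor((v[, 1] - lo[1]) / mm_per_pixel), inner[1] - 1) + pad
    cy <- pmin(floor((v[, 2] - lo[2]) / mm_per_pixel), inner[2] - 1) + pad
    cbind(cx, cy)
  }
  px <- to_px(verts)
  img <- matrix(0L, nrow = ny, ncol = nx)
  for (i in seq_len(nrow(px) - 1)) {
    seg <- bresenham(px[i, 1], px[i, 2], px[i + 1, 1], px[i + 1, 2])
    img[cbind(seg[, 2] + 1L, seg[, 1] + 1L)] <- 1L
  }
  list(image = img,
       origin = c(lo[1] + (0.5 - pad) * mm_per_pixel,
                  lo[2] + (0.5 - pad) * mm_per_pixel),
       mm_per_pixel = mm_per_pixel)
}

bresenham <- function(x0, y0, x1, y1) {
  dx <- abs(x1 - x0); dy <- -abs(y1 - y0)
  sx <- if (x0 < x1) 1L else -1L
  sy <- if (y0 < y1) 1L else -1L
  err <- dx + dy
  out <- matrix(integer(0), 0, 2)
  x <- x0; y <- y0
  repeat {
    out <- rbind(out, c(x, y))
    if (x == x1 && y == y1) break
    e2 <- 2 * err
    if (e2 >= dy) { err <- err + dy; x <- x + sx }
    if (e2 <= dx) { err <- err + dx; y <- y + sy }
  }
  out
}
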