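#' Build a scalable shape model from a contour template
#'
#' Runs the template preprocessing chain: threshold segmentation, connected
#' components, hole filling, an area filter that must leave exactly one
#' component, outer-contour extraction, and conversion of the contour to
#' model edge points with outward unit normals. The model is replicated over
#' an image pyramid (coordinates halve per level, point counts shrink) so
#' that matching can run coarse-to-fine.
#'
#' Pixel coordinates inside the matching modules are `(x, y) = (column, row)`
#' in R's 1-based indexing; a pose's translation is the image position of the
#' template origin (the model centroid).
#'
#' @param template binary or grayscale contour image matrix (rows x cols).
#' @param pyramid_levels number of pyramid levels (>= 1, default 4).
#' @param angle_range rotation search range in degrees, `c(min, max)`.
#' @param angle_step rotation step in degrees at the finest level; coarser
#'   levels double it per level.
#' @param scale_range isotropic scale search range `c(min, max)`.
#' @param scale_step scale step.
#' @param threshold segmentation threshold; default half the image maximum.
#' @param area_range component area window in pixels; components outside it
#'   are dropped. The default keeps components at least half as large as the
#'   largest one.
#' @param max_points model point budget at the finest level (halves per
#'   coarser level, floor 8).
#' @return An object of class `shape_model`.
#' @export
build_shape_model <- function(template, pyramid_levels = 4,
                              angle_range = c(-180, 180), angle_step = 2,
                              scale_range = c(0.9, 1.1), scale_step = 0.05,
                              threshold = NULL, area_range = NULL,
                              max_points = 512) {
  img <- as.matrix(template)
  storage.mode(img) <- "double"
  if (pyramid_levels < 1) stop("pyramid_levels must be >= 1")
  if (is.null(threshold)) threshold <- max(img) / 2
  mask <- img > threshold
  if (!any(mask)) stop("model-build error: no foreground after thresholding")

  # connect adjacent fragments (closing), then fill enclosed areas: the
  # outline is 8-connected so holes are filled by flooding the 4-connected
  # background from the border
  mask <- closing_1px(mask)
  mask <- fill_holes(mask)
  lab <- EBImage::bwlabel(EBImage::Image(t(mask)))
  areas <- table(as.integer(EBImage::imageData(lab)))
  areas <- areas[names(areas) != "0"]
  if (is.null(area_range)) area_range <- c(max(areas) / 2, Inf)
  keep <- names(areas)[areas >= area_range[1] & areas <= area_range[2]]
  if (length(keep) != 1)
    stop(sprintf("model-build error: %d component(s) survive the area filter",
                 length(keep)))
  sel <- EBImage::imageData(lab) == as.integer(keep)

  # ocontour wants an Image in EBImage's (x, y) layout, which t(mask) is
  oc <- EBImage::ocontour(EBImage::Image(sel))[[1]]
  # 0-based (x, y); convert to 1-based (col, row) matching t(mask) layout
  contour <- oc + 1
  colnames(contour) <- c("x", "y")
  if (nrow(contour) < 8) stop("model-build error: contour too short")

  nrm <- contour_normals(contour)
  # the traced contour runs on foreground pixels; the intensity step (where
  # image gradients peak) lies half a pixel further out
  contour <- contour + 0.5 * nrm
  centroid <- colMeans(contour)

  n0 <- min(max_points, nrow(contour))
  levels <- vector("list", pyramid_levels)
  for (lev in seq_len(pyramid_levels)) {
    budget <- max(8L, ceiling(n0 / 2^(lev - 1)))
    pick <- unique(round(seq(1, nrow(contour), length.out = min(budget, nrow(contour)))))
    levels[[lev]] <- list(
      points = sweep(contour[pick, , drop = FALSE], 2, centroid) / 2^(lev - 1),
      normals = nrm[pick, , drop = FALSE])
  }
  structure(list(levels = levels, origin = centroid,
                 contour = sweep(contour, 2, centroid),
                 angle_range = angle_range, angle_step = angle_step,
                 scale_range = scale_range, scale_step = scale_step),
            class = "shape_model")
}

# outward unit normals from the ordered contour trace; the trace is smoothed
# with a short circular moving average first (pixel staircase suppression)
# and orientation is fixed by a majority vote against the centroid direction
contour_normals <- function(contour, smooth = 5L, w = 3L) {
  n <- nrow(contour)
  sm <- contour
  if (n > 2 * smooth) {
    half <- smooth %/% 2
    idx <- outer(seq_len(n) - 1, -half:half, "+") %% n + 1
    sm <- cbind(rowMeans(matrix(contour[idx, 1], n)),
                rowMeans(matrix(contour[idx, 2], n)))
  }
  nxt <- ((seq_len(n) - 1 + w) %% n) + 1
  prv <- ((seq_len(n) - 1 - w) %% n) + 1
  tang <- sm[nxt, , drop = FALSE] - sm[prv, , drop = FALSE]
  len <- sqrt(rowSums(tang^2))
  len[len == 0] <- 1
  tang <- tang / len
  nrm <- cbind(tang[, 2], -tang[, 1])
  centroid <- colMeans(contour)
  outward <- rowSums(nrm * sweep(contour, 2, centroid))
  if (sum(outward > 0) < n / 2) nrm <- -nrm
  nrm
}

#' @export
print.shape_model <- function(x, ...) {
  cat(sprintf(paste0("shape_model: %d pyramid level(s), %d points at finest; ",
                     "angles [%g, %g] deg step %g, scales [%g, %g] step %g\n"),
              length(x$levels), nrow(x$levels[[1]]$points),
              x$angle_range[1], x$angle_range[2], x$angle_step,
              x$scale_range[1], x$scale_range[2], x$scale_step))
  invisible(x)
}

#' Sub-pixel edge extraction
#'
#' Sobel gradients, non-maximum suppression along the quantized gradient
#' direction, hysteresis linking (weak edges survive only in components that
#' contain a strong edge) and a parabolic sub-pixel correction along the
#' gradient. Thresholds apply to the Sobel gradient magnitude.
#'
#' @param image grayscale matrix (rows x cols).
#' @param low,high hysteresis thresholds, `0 < low <= high`. Defaults are
#'   fractions (0.1 / 0.25) of the maximum gradient magnitude.
#' @return An object of class `edge_image`: `points` (N x 2 sub-pixel
#'   `(x, y)` coordinates, 1-based), `normals` (unit gradient directions),
#'   `size` `c(rows, cols)`.
#' @export
edge_image <- function(image, low = NULL, high = NULL) {
  img <- as.matrix(image)
  storage.mode(img) <- "double"
  g <- sobel_gradients(img)
  mag <- sqrt(g$gx^2 + g$gy^2)
  if (is.null(high)) high <- 0.25 * max(mag)
  if (is.null(low)) low <- 0.4 * high
  if (!(low > 0 && low <= high)) stop("need 0 < low <= high")

  nr <- nrow(img); nc <- ncol(img)
  # non-maximum suppression along the gradient, 4 quantized directions
  ang <- atan2(g$gy, g$gx)
  sector <- (round(ang / (pi / 4)) %% 4)   # 0:E/W 1:NE/SW 2:N/S 3:NW/SE
  off <- list(c(0, 1), c(1, 1), c(1, 0), c(1, -1))  # (drow, dcol)
  keep <- matrix(FALSE, nr, nc)
  inner_r <- 2:(nr - 1); inner_c <- 2:(nc - 1)
  for (s in 0:3) {
    d <- off[[s + 1]]
    m0 <- mag[inner_r, inner_c]
    mp <- mag[inner_r + d[1], inner_c + d[2]]
    mm <- mag[inner_r - d[1], inner_c - d[2]]
    ok <- sector[inner_r, inner_c] == s & m0 >= mp & m0 > mm & m0 >= low
    keep[inner_r, inner_c] <- keep[inner_r, inner_c] | ok
  }
  if (!any(keep)) return(empty_edge_image(nr, nc))

  # hysteresis: keep weak ridge pixels only in components containing a strong one
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(t(keep))))
  lab <- t(lab)
  strong_labels <- unique(lab[keep & mag >= high])
  strong_labels <- strong_labels[strong_labels != 0]
  keep <- keep & lab %in% strong_labels
  dim(keep) <- c(nr, nc)
  idx <- which(keep, arr.ind = TRUE)
  if (nrow(idx) == 0) return(empty_edge_image(nr, nc))

  m0 <- mag[idx]
  sec <- sector[idx]
  dsub <- numeric(nrow(idx))
  for (s in 0:3) {
    d <- off[[s + 1]]
    rows <- which(sec == s)
    if (!length(rows)) next
    rr <- idx[rows, 1]; cc <- idx[rows, 2]
    mp <- mag[cbind(rr + d[1], cc + d[2])]
    mm <- mag[cbind(rr - d[1], cc - d[2])]
    den <- mm - 2 * m0[rows] + mp
    dsub[rows] <- ifelse(abs(den) > 1e-12, 0.5 * (mm - mp) / den, 0)
  }
  dsub <- pmin(pmax(dsub, -0.5), 0.5)
  gx <- g$gx[idx]; gy <- g$gy[idx]
  gl <- sqrt(gx^2 + gy^2)
  nrms <- cbind(gx / gl, gy / gl)
  dirs <- t(vapply(sec + 1, function(s) off[[s]], numeric(2)))  # (drow, dcol)
  pts <- cbind(x = idx[, 2] + dsub * dirs[, 1 + 1],
               y = idx[, 1] + dsub * dirs[, 1])
  structure(list(points = pts, normals = nrms, size = c(nr, nc)),
            class = "edge_image")
}

empty_edge_image <- function(nr, nc) {
  structure(list(points = matrix(numeric(0), 0, 2,
                                 dimnames = list(NULL, c("x", "y"))),
                 normals = matrix(numeric(0), 0, 2), size = c(nr, nc)),
            class = "edge_image")
}

#' @export
print.edge_image <- function(x, ...) {
  cat(sprintf("edge_image: %d edge points in a %d x %d image\n",
              nrow(x$points), x$size[1], x$size[2]))
  invisible(x)
}

sobel_gradients <- function(img) {
  nr <- nrow(img); nc <- ncol(img)
  pad <- rbind(img[1, ], img, img[nr, ])
  pad <- cbind(pad[, 1], pad, pad[, nc])
  sh <- function(dr, dc) pad[(2 + dr):(nr + 1 + dr), (2 + dc):(nc + 1 + dc)]
  gx <- (sh(-1, 1) + 2 * sh(0, 1) + sh(1, 1) -
           sh(-1, -1) - 2 * sh(0, -1) - sh(1, -1)) / 8
  gy <- (sh(1, -1) + 2 * sh(1, 0) + sh(1, 1) -
           sh(-1, -1) - 2 * sh(-1, 0) - sh(-1, 1)) / 8
  list(gx = gx, gy = gy)   # gx: d/dcol, gy: d/drow
}

# fill regions enclosed by (possibly 8-connected) outlines: any background
# component not reaching the image border is interior
fill_holes <- function(m) {
  bg <- !m
  lab <- t(EBImage::imageData(EBImage::bwlabel(EBImage::Image(t(bg)))))
  border_labs <- setdiff(unique(c(lab[1, ], lab[nrow(lab), ],
                                  lab[, 1], lab[, ncol(lab)])), 0)
  outside <- bg & matrix(lab %in% border_labs, nrow(m), ncol(m))
  !outside
}

closing_1px <- function(m) {
  brush <- EBImage::makeBrush(3, shape = "box")
  t(EBImage::imageData(EBImage::closing(EBImage::Image(t(m)), brush))) > 0
}

mean_pool2 <- function(img) {
  nr <- 2 * (nrow(img) %/% 2); nc <- 2 * (ncol(img) %/% 2)
  img <- img[seq_len(nr), seq_len(nc), drop = FALSE]
  (img[seq(1, nr, 2), seq(1, nc, 2)] + img[seq(2, nr, 2), seq(1, nc, 2)] +
     img[seq(1, nr, 2), seq(2, nc, 2)] + img[seq(2, nr, 2), seq(2, nc, 2)]) / 4
}
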