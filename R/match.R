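#' Pose of a matched template
#'
#' @param theta rotation in radians.
#' @param tx,ty image position (1-based pixels) of the template origin.
#' @param scale isotropic scale factor (> 0).
#' @param score gradient-direction similarity in `[0, 1]`.
#' @return An object of class `pod_pose`.
#' @export
pod_pose <- function(theta = 0, tx = 0, ty = 0, scale = 1, score = NA_real_) {
  if (!(scale > 0)) stop("scale must be positive")
  if (!is.na(score) && (score < 0 || score > 1))
    stop("score must lie in [0, 1]")
  structure(list(theta = unname(theta), tx = unname(tx), ty = unname(ty),
                 scale = unname(scale), score = unname(score)),
            class = "pod_pose")
}

#' @export
print.pod_pose <- function(x, ...) {
  cat(sprintf("pod_pose: theta %.2f deg, t (%.2f, %.2f) px, scale %.3f, score %.3f\n",
              x$theta * 180 / pi, x$tx, x$ty, x$scale, x$score))
  invisible(x)
}

rot2 <- function(theta) {
  matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
}

transform_points <- function(pts, pose) {
  sweep(pts %*% t(rot2(pose$theta)) * pose$scale, 2,
        c(pose$tx, pose$ty), "+")
}

# normalized gradient fields of an image, zeroed where the magnitude is tiny
gradient_fields <- function(img) {
  g <- sobel_gradients(img)
  mag <- sqrt(g$gx^2 + g$gy^2)
  floorv <- 1e-6 * max(mag, 1e-300)
  s <- ifelse(mag > floorv, 1 / mag, 0)
  list(gxn = g$gx * s, gyn = g$gy * s)
}

# score one pose: mean over model points of |cos| between the rotated model
# normal and the image gradient direction at the transformed point
score_pose <- function(fields, pts, normals, pose) {
  q <- transform_points(pts, pose)
  R <- rot2(pose$theta)
  n <- normals %*% t(R)
  cc <- round(q[, 1]); rr <- round(q[, 2])
  nr <- nrow(fields$gxn); ncol_ <- ncol(fields$gxn)
  inside <- rr >= 1 & rr <= nr & cc >= 1 & cc <= ncol_
  if (!any(inside)) return(0)
  ii <- cbind(rr[inside], cc[inside])
  vals <- abs(fields$gxn[ii] * n[inside, 1] + fields$gyn[ii] * n[inside, 2])
  sum(vals) / nrow(pts)
}

#' Find template instances by coarse-to-fine pyramid search
#'
#' Exhaustively scores every translation at the coarsest pyramid level over
#' the model's rotation/scale grid, then tracks the best candidates down the
#' pyramid with a local pose search at each level. The similarity at a pose
#' is the mean over model points of the absolute normalized dot product
#' between the transformed model normal and the image gradient direction
#' (polarity-tolerant gradient-direction score, bounded in `[0, 1]`).
#' Overlapping detections are suppressed greedily by descending score.
#'
#' @param model a [build_shape_model()].
#' @param image grayscale matrix (rows x cols).
#' @param min_score minimum similarity in `(0, 1]` for a reported match.
#' @param max_matches maximum number of poses returned.
#' @param max_overlap maximum pairwise bounding-box overlap (intersection
#'   over smaller box) between reported matches.
#' @return List of [pod_pose()] objects sorted by descending score (possibly
#'   empty).
#' @export
find_matches <- function(model, image, min_score = 0.7, max_matches = 10,
                         max_overlap = 0.2) {
  if (!(min_score > 0 && min_score <= 1)) stop("min_score must be in (0, 1]")
  img <- as.matrix(image)
  storage.mode(img) <- "double"
  L <- length(model$levels)
  pyr <- vector("list", L)
  pyr[[1]] <- img
  if (L > 1) for (lev in 2:L) pyr[[lev]] <- mean_pool2(pyr[[lev - 1]])
  fields <- lapply(pyr, gradient_fields)

  angles <- seq(model$angle_range[1], model$angle_range[2],
                by = model$angle_step * 2^(L - 1)) * pi / 180
  if (abs((model$angle_range[2] - model$angle_range[1]) - 360) < 1e-9)
    angles <- angles[-length(angles)]  # -180 and 180 coincide
  scales <- seq(model$scale_range[1], model$scale_range[2],
                by = model$scale_step)

  cands <- coarse_scan(fields[[L]], model$levels[[L]], angles, scales,
                       relax = 0.85 * min_score,
                       top = max(4 * max_matches, 16))
  if (length(cands) == 0) return(list())

  if (L > 1) for (lev in (L - 1):1) {
    step <- model$angle_step * 2^(lev - 1) * pi / 180
    cands <- lapply(cands, function(cd) {
      refine_candidate(fields[[lev]], model$levels[[lev]], cd, step,
                       model$scale_step / 2, model$scale_range)
    })
  }
  cands <- Filter(function(cd) cd$score >= min_score, cands)
  if (length(cands) == 0) return(list())
  cands <- cands[order(-vapply(cands, function(cd) cd$score, numeric(1)))]
  keep <- nms_poses(cands, model, max_overlap)
  keep <- keep[seq_len(min(length(keep), max_matches))]
  lapply(keep, function(cd) pod_pose(cd$theta, cd$tx, cd$ty, cd$scale, cd$score))
}

coarse_scan <- function(field, level, angles, scales, relax, top) {
  pts <- level$points; nrms <- level$normals
  nr <- nrow(field$gxn); nc <- ncol(field$gxn)
  out <- list()
  for (th in angles) for (s in scales) {
    R <- rot2(th)
    q <- pts %*% t(R) * s
    n <- nrms %*% t(R)
    ox <- round(q[, 1]); oy <- round(q[, 2])
    tx_lo <- 1 - min(ox); tx_hi <- nc - max(ox)
    ty_lo <- 1 - min(oy); ty_hi <- nr - max(oy)
    if (tx_hi < tx_lo || ty_hi < ty_lo) next
    h <- ty_hi - ty_lo + 1; w <- tx_hi - tx_lo + 1
    acc <- matrix(0, h, w)
    for (i in seq_len(nrow(pts))) {
      rows <- (ty_lo + oy[i]):(ty_hi + oy[i])
      cols <- (tx_lo + ox[i]):(tx_hi + ox[i])
      acc <- acc + abs(field$gxn[rows, cols, drop = FALSE] * n[i, 1] +
                         field$gyn[rows, cols, drop = FALSE] * n[i, 2])
    }
    acc <- acc / nrow(pts)
    pk <- local_maxima(acc, relax)
    if (nrow(pk)) {
      for (j in seq_len(nrow(pk)))
        out[[length(out) + 1]] <- list(theta = th, tx = tx_lo + pk[j, 2] - 1,
                                       ty = ty_lo + pk[j, 1] - 1, scale = s,
                                       score = acc[pk[j, 1], pk[j, 2]])
    }
  }
  if (length(out) == 0) return(list())
  out <- out[order(-vapply(out, function(cd) cd$score, numeric(1)))]
  out[seq_len(min(length(out), top))]
}

local_maxima <- function(acc, thresh) {
  h <- nrow(acc); w <- ncol(acc)
  if (h < 1 || w < 1) return(matrix(integer(0), 0, 2))
  pad <- matrix(-Inf, h + 2, w + 2)
  pad[2:(h + 1), 2:(w + 1)] <- acc
  ge <- function(dr, dc) pad[2:(h + 1), 2:(w + 1)] >=
    pad[(2 + dr):(h + 1 + dr), (2 + dc):(w + 1 + dc)]
  ok <- acc >= thresh & ge(-1, -1) & ge(-1, 0) & ge(-1, 1) & ge(0, -1) &
    ge(0, 1) & ge(1, -1) & ge(1, 0) & ge(1, 1)
  which(ok, arr.ind = TRUE)
}

# local pose-grid search around a candidate lifted from the next-coarser level
refine_candidate <- function(field, level, cd, angle_step, scale_step,
                             scale_range) {
  best <- NULL
  for (th in cd$theta + angle_step * (-1:1))
    for (s in pmin(pmax(cd$scale + scale_step * (-1:1), scale_range[1]),
                   scale_range[2]))
      for (dx in -2:2) for (dy in -2:2) {
        pose <- list(theta = th, tx = round(2 * cd$tx - 0.5) + dx,
                     ty = round(2 * cd$ty - 0.5) + dy, scale = s)
        sc <- score_pose(field, level$points, level$normals,
                         pod_pose(pose$theta, pose$tx, pose$ty, pose$scale))
        if (is.null(best) || sc > best$score)
          best <- list(theta = th, tx = pose$tx, ty = pose$ty, scale = s,
                       score = sc)
      }
  best
}

nms_poses <- function(cands, model, max_overlap) {
  boxes <- lapply(cands, function(cd) {
    q <- transform_points(model$levels[[1]]$points,
                          pod_pose(cd$theta, cd$tx, cd$ty, cd$scale))
    c(min(q[, 1]), min(q[, 2]), max(q[, 1]), max(q[, 2]))
  })
  keep <- list(); kept_boxes <- list()
  for (i in seq_along(cands)) {
    b <- boxes[[i]]
    ok <- TRUE
    for (kb in kept_boxes) {
      ix <- max(0, min(b[3], kb[3]) - max(b[1], kb[1]))
      iy <- max(0, min(b[4], kb[4]) - max(b[2], kb[2]))
      inter <- ix * iy
      amin <- min((b[3] - b[1]) * (b[4] - b[2]),
                  (kb[3] - kb[1]) * (kb[4] - kb[2]))
      if (amin > 0 && inter / amin > max_overlap) { ok <- FALSE; break }
    }
    if (ok) { keep[[length(keep) + 1]] <- cands[[i]]
              kept_boxes[[length(kept_boxes) + 1]] <- b }
  }
  keep
}

#' Least-squares sub-pixel pose refinement
#'
#' Iteratively minimizes the sum of squared point-to-tangent distances
#' between transformed model points and their corresponding image edge
#' points: each residual is `((W m_i) - e_i) . n_i` with `W` the linearized
#' (small-angle) rigid update of the pose, solved as a 3-unknown linear least
#' squares in `(dtheta, dx, dy)` and iterated with re-matching.
#' Correspondences are the nearest edge points along each transformed model
#' normal. The scale is held fixed (the discrete scale sweep of
#' [find_matches()] handles it). The mean absolute normal-distance residual
#' is guaranteed non-increasing: an iteration that would raise it is rolled
#' back and the refinement stops.
#'
#' @param model a [build_shape_model()].
#' @param edges an [edge_image()] of the target.
#' @param init initial [pod_pose()] (score must be positive).
#' @param iterations maximum Gauss-Newton iterations.
#' @param search_radius correspondence search radius in pixels.
#' @return The refined [pod_pose()] (score copied from `init`), with
#'   attributes `residual` (final mean |distance|) and `degenerate` (TRUE
#'   when fewer than 3 correspondences were found and `init` was returned).
#' @export
refine_pose <- function(model, edges, init, iterations = 10,
                        search_radius = 5) {
  if (nrow(edges$points) == 0) stop("edge image is empty")
  if (!is.na(init$score) && init$score <= 0)
    stop("initial pose score must be positive")
  pts <- model$levels[[1]]$points
  nrms <- model$levels[[1]]$normals
  E <- edges$points

  pose <- init
  co <- correspondences(pts, nrms, pose, E, search_radius)
  if (co$n < 3) {
    out <- init
    attr(out, "degenerate") <- TRUE
    attr(out, "residual") <- NA_real_
    return(out)
  }
  res <- co$mean_abs
  trace <- res
  conv_tol <- 1e-3
  for (it in seq_len(iterations)) {
    m <- co$m; e <- co$e; nn <- co$n_vec
    rel <- sweep(m, 2, c(pose$tx, pose$ty))
    a1 <- -rel[, 2] * nn[, 1] + rel[, 1] * nn[, 2]   # (J rel) . n
    A <- cbind(a1, nn[, 1], nn[, 2])
    b <- rowSums((e - m) * nn)
    upd <- tryCatch(qr.solve(A, b), error = function(err) NULL)
    if (is.null(upd)) break
    cand <- pose
    cand$theta <- pose$theta + upd[1]
    cand$tx <- pose$tx + upd[2]
    cand$ty <- pose$ty + upd[3]
    co_new <- correspondences(pts, nrms, cand, E, search_radius)
    if (co_new$n < 3 || co_new$mean_abs > res) break
    pose <- cand
    co <- co_new
    res <- co_new$mean_abs
    trace <- c(trace, res)
    if (max(abs(upd)) < conv_tol) break
  }
  out <- pod_pose(pose$theta, pose$tx, pose$ty, pose$scale, init$score)
  attr(out, "residual") <- res
  attr(out, "residual_trace") <- trace
  attr(out, "degenerate") <- FALSE
  out
}

correspondences <- function(pts, nrms, pose, E, radius) {
  m <- transform_points(pts, pose)
  R <- rot2(pose$theta)
  n <- nrms %*% t(R)
  cand <- radius_grid(E, m, radius)
  rows <- integer(0); me <- NULL; ee <- NULL; nv <- NULL
  sel_e <- rep(NA_integer_, nrow(m))
  for (i in seq_len(nrow(m))) {
    ci <- cand[[i]]
    if (length(ci) == 0) next
    off <- sweep(E[ci, , drop = FALSE], 2, m[i, ])
    perp <- abs(off[, 1] * (-n[i, 2]) + off[, 2] * n[i, 1])
    d2 <- rowSums(off^2)
    near_ray <- perp <= 1.5
    pickable <- if (any(near_ray)) ci[near_ray][which.min(d2[near_ray])]
                else ci[which.min(d2)]
    sel_e[i] <- pickable
  }
  ok <- which(!is.na(sel_e))
  if (length(ok) == 0)
    return(list(n = 0, mean_abs = Inf))
  m_ok <- m[ok, , drop = FALSE]
  e_ok <- E[sel_e[ok], , drop = FALSE]
  n_ok <- n[ok, , drop = FALSE]
  resid <- rowSums((m_ok - e_ok) * n_ok)
  list(n = length(ok), m = m_ok, e = e_ok, n_vec = n_ok,
       mean_abs = mean(abs(resid)))
}

#' Extract the matched region from the image
#'
#' Fills the interior of the pose-transformed model contour and returns the
#' binary mask plus the cropped sub-image over its bounding box. A contour
#' partially outside the image is clipped with a warning.
#'
#' @param image grayscale matrix.
#' @param model a [build_shape_model()].
#' @param pose a [pod_pose()].
#' @return List with `mask` (logical matrix, image-sized), `crop` (sub-image
#'   over the mask bounding box), `bbox` `c(row0, col0, row1, col1)`.
#' @export
extract_region <- function(image, model, pose) {
  img <- as.matrix(image)
  nr <- nrow(img); nc <- ncol(img)
  poly <- transform_points(model$contour, pose)
  if (any(poly[, 1] < 1 | poly[, 1] > nc | poly[, 2] < 1 | poly[, 2] > nr))
    warning("transformed contour extends outside the image; mask clipped")
  mask <- matrix(FALSE, nr, nc)
  px <- pmin(pmax(round(poly[, 1]), 1), nc)
  py <- pmin(pmax(round(poly[, 2]), 1), nr)
  closed <- rbind(cbind(px, py), c(px[1], py[1]))
  for (i in seq_len(nrow(closed) - 1)) {
    seg <- bresenham(closed[i, 1], closed[i, 2], closed[i + 1, 1], closed[i + 1, 2])
    mask[cbind(seg[, 2], seg[, 1])] <- TRUE
  }
  mask <- fill_holes(mask)
  if (!any(mask)) stop("pose produced an empty mask")
  rr <- range(which(rowSums(mask) > 0))
  cc <- range(which(colSums(mask) > 0))
  list(mask = mask,
       crop = img[rr[1]:rr[2], cc[1]:cc[2], drop = FALSE],
       bbox = c(rr[1], cc[1], rr[2], cc[2]))
}

#' Morphological opening of a binary mask
#'
#' Erosion followed by dilation with a disk structuring element; removes
#' burrs and protrusions smaller than the disk while preserving bulk shape.
#' Anti-extensive (the result is a subset of the input) and idempotent.
#'
#' @param mask logical or 0/1 matrix.
#' @param se_radius disk radius in pixels (>= 1).
#' @return Logical matrix of the opened mask.
#' @export
open_mask <- function(mask, se_radius = 2) {
  if (se_radius < 1) stop("se_radius must be >= 1")
  m <- as.matrix(mask) > 0
  brush <- EBImage::makeBrush(2 * se_radius + 1, shape = "disc")
  opened <- EBImage::opening(EBImage::Image(t(m)), brush)
  t(EBImage::imageData(opened)) > 0
}
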