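#' Pod morphology presets
#'
#' Base dimensions (mm) of the five pod shape classes handled by the
#' pipeline: common, axe (asymmetric lobes), cocoon (compact, barely
#' pinched), wasp-waist (strongly pinched) and lollipop (long neck between
#' unequal lobes). Sizes are typical of real pods: lobe radii 7-13 mm,
#' lengths 30-45 mm.
#'
#' @return Named list of parameter lists (`r1`, `r2`, `sep`, `waist`,
#'   `bump_amp`, `bump_freq`).
#' @export
pod_morphologies <- function() {
  list(
    common     = list(r1 = 11.0, r2 = 10.5, sep = 16, waist = 0.85),
    axe        = list(r1 = 13.0, r2 = 8.5,  sep = 14, waist = 0.88),
    cocoon     = list(r1 = 11.5, r2 = 11.0, sep = 9,  waist = 0.96),
    wasp_waist = list(r1 = 11.0, r2 = 10.5, sep = 20, waist = 0.55),
    lollipop   = list(r1 = 12.0, r2 = 7.0,  sep = 26, waist = 0.80)
  )
}

#' Specify one synthetic pod
#'
#' A pod is a surface of revolution around a horizontal axis: two spherical
#' lobe caps of radii `r1`, `r2` whose centers are `sep` apart, joined by a
#' smooth (Hermite) radius blend, multiplicatively pinched at the middle by
#' the `waist` factor, with a sinusoidal radius modulation emulating shell
#' surface texture. The pod rests on the table (z = 0) and is posed by a 2D
#' `position` and a `yaw` about the vertical.
#'
#' @param morphology one of `names(pod_morphologies())`.
#' @param r1,r2 lobe radii (mm); defaults from the morphology preset.
#' @param sep lobe center separation (mm).
#' @param waist waist pinch factor in `(0, 1]` (1 = no pinch).
#' @param bump_amp surface bump amplitude (mm, must stay below
#'   `min(r1, r2)/4`).
#' @param bump_freq bump count along the axis.
#' @param position length-2 table position of the pod center (mm).
#' @param yaw rotation about +Z (radians).
#' @return An object of class `pod_spec`.
#' @export
pod_spec <- function(morphology = "common", r1 = NULL, r2 = NULL, sep = NULL,
                     waist = NULL, bump_amp = 0.25, bump_freq = 6,
                     position = c(0, 0), yaw = 0) {
  presets <- pod_morphologies()
  if (!morphology %in% names(presets))
    stop("unknown morphology: ", morphology, " (expected one of ",
         paste(names(presets), collapse = ", "), ")")
  base <- presets[[morphology]]
  r1 <- if (is.null(r1)) base$r1 else r1
  r2 <- if (is.null(r2)) base$r2 else r2
  sep <- if (is.null(sep)) base$sep else sep
  waist <- if (is.null(waist)) base$waist else waist
  if (r1 <= 0 || r2 <= 0) stop("lobe radii must be positive")
  if (!(waist > 0 && waist <= 1)) stop("waist factor must be in (0, 1]")
  if (bump_amp < 0 || bump_amp >= min(r1, r2) / 4)
    stop("bump amplitude must be < min(r1, r2)/4")
  spec <- structure(list(morphology = morphology, r1 = r1, r2 = r2, sep = sep,
                         waist = waist, bump_amp = bump_amp,
                         bump_freq = bump_freq,
                         position = as.numeric(position), yaw = yaw),
                    class = "pod_spec")
  spec$length <- r1 + sep + r2
  # resting height of the axis = maximal effective radius (pod touches z = 0)
  ugrid <- seq(0, spec$length, length.out = 4001)
  spec$axis_height <- max(pod_radius(spec, ugrid))
  spec
}

#' @export
print.pod_spec <- function(x, ...) {
  cat(sprintf(paste0("pod_spec '%s': lobes %.1f/%.1f mm, sep %.1f, waist %.2f, ",
                     "length %.1f mm, at (%.1f, %.1f) yaw %.1f deg\n"),
              x$morphology, x$r1, x$r2, x$sep, x$waist, x$length,
              x$position[1], x$position[2], x$yaw * 180 / pi))
  invisible(x)
}

#' Effective profile radius of a pod
#'
#' Radius of the circular cross-section at axial coordinate `u` in
#' `[0, length]`: spherical caps at both ends, a Hermite blend between lobe
#' radii in the middle, a Gaussian-window waist pinch, and the sinusoidal
#' bump modulation.
#'
#' @param spec a [pod_spec()].
#' @param u axial coordinates (mm), vectorized.
#' @return radii (mm), 0 outside `[0, length]`.
#' @export
pod_radius <- function(spec, u) {
  u1 <- spec$r1
  u2 <- spec$r1 + spec$sep
  rho <- numeric(length(u))
  cap1 <- u < u1
  rho[cap1] <- sqrt(pmax(0, spec$r1^2 - (u1 - u[cap1])^2))
  cap2 <- u > u2
  rho[cap2] <- sqrt(pmax(0, spec$r2^2 - (u[cap2] - u2)^2))
  mid <- !cap1 & !cap2
  if (any(mid)) {
    h <- if (spec$sep > 0) (u[mid] - u1) / spec$sep else rep(0.5, sum(mid))
    rho[mid] <- spec$r1 + (spec$r2 - spec$r1) * h^2 * (3 - 2 * h)
  }
  if (spec$waist < 1 && spec$sep > 0) {
    um <- (u1 + u2) / 2
    sw <- spec$sep / 4
    rho <- rho * (1 - (1 - spec$waist) * exp(-((u - um) / sw)^2))
  }
  if (spec$bump_amp > 0) {
    rel <- spec$bump_amp / max(spec$r1, spec$r2)
    rho <- rho * (1 + rel * sin(2 * pi * spec$bump_freq * u / spec$length))
  }
  rho[u < 0 | u > spec$length] <- 0
  rho
}

# world (x, y) -> pod-local axial/lateral coordinates
pod_local <- function(spec, x, y) {
  dx <- x - spec$position[1]
  dy <- y - spec$position[2]
  cs <- cos(spec$yaw); sn <- sin(spec$yaw)
  list(u = (cs * dx + sn * dy) + spec$length / 2,
       w = -sn * dx + cs * dy)
}

#' Top-surface height field of one pod
#'
#' For world coordinates `(x, y)`, the height of the pod's upper surface
#' (mm above the table), the lower surface, and the vertical component of
#' the upper-surface normal. Points outside the silhouette get `NA`.
#'
#' @param spec a [pod_spec()].
#' @param x,y world coordinates (vectorized, equal length).
#' @return List with `z`, `zlow`, `nz` and logical `inside`.
#' @export
pod_height <- function(spec, x, y) {
  loc <- pod_local(spec, x, y)
  rho <- pod_radius(spec, loc$u)
  inside <- loc$u >= 0 & loc$u <= spec$length & abs(loc$w) < rho
  z <- zlow <- nz <- rep(NA_real_, length(x))
  if (any(inside)) {
    half <- sqrt(pmax(0, rho[inside]^2 - loc$w[inside]^2))
    z[inside] <- spec$axis_height + half
    zlow[inside] <- spec$axis_height - half
    nz[inside] <- half / rho[inside]
  }
  list(z = z, zlow = zlow, nz = nz, inside = inside)
}

#' Evaluate a multi-pod scene's visible surface
#'
#' Height of the highest surface at each `(x, y)` plus which pod it belongs
#' to (0 = no pod). This is the upper envelope a top-down camera sees, so
#' mutual occlusion between touching pods is reproduced by construction.
#'
#' @param pods list of [pod_spec()].
#' @param x,y world coordinates (vectorized).
#' @return List with `z` (`-Inf` where no pod), `id` (0 where no pod), `nz`.
#' @export
scene_surface <- function(pods, x, y) {
  n <- length(x)
  z <- rep(-Inf, n); id <- integer(n); nz <- rep(NA_real_, n)
  for (i in seq_along(pods)) {
    h <- pod_height(pods[[i]], x, y)
    better <- h$inside & h$z > z
    z[better] <- h$z[better]
    nz[better] <- h$nz[better]
    id[better] <- i
  }
  list(z = z, id = id, nz = nz)
}

#' Sample points on a pod surface
#'
#' Uniform random parameter sampling of the analytic surface; every returned
#' point lies exactly on the surface of revolution.
#'
#' @param spec a [pod_spec()].
#' @param samples number of points (>= 500).
#' @param seed RNG seed (sampling is reproducible).
#' @return List with `points` (world-frame N x 3) and `spec`.
#' @export
make_pod_surface <- function(spec, samples = 4000, seed = 1) {
  if (samples < 500) stop("samples must be >= 500")
  with_seed(seed, {
    u <- stats::runif(samples, 0, spec$length)
    phi <- stats::runif(samples, 0, 2 * pi)
    rho <- pod_radius(spec, u)
    lx <- u - spec$length / 2
    w <- rho * cos(phi)
    z <- spec$axis_height + rho * sin(phi)
    cs <- cos(spec$yaw); sn <- sin(spec$yaw)
    pts <- cbind(spec$position[1] + cs * lx - sn * w,
                 spec$position[2] + sn * lx + cs * w,
                 z)
    list(points = pts, spec = spec)
  })
}

#' Radial residual of points against a pod's analytic surface
#'
#' Signed distance along the cross-section radial direction: 0 for points on
#' the surface.
#'
#' @param spec a [pod_spec()].
#' @param points N x 3 world points.
#' @return Numeric vector of residuals (mm); `NA` outside the axial range.
#' @export
surface_residual <- function(spec, points) {
  points <- as_xyz_matrix(points)
  loc <- pod_local(spec, points[, 1], points[, 2])
  rad <- sqrt(loc$w^2 + (points[, 3] - spec$axis_height)^2)
  rho <- pod_radius(spec, loc$u)
  out <- rad - rho
  out[loc$u < 0 | loc$u > spec$length] <- NA_real_
  out
}

#' Analytic silhouette area of a pod
#' @param spec a [pod_spec()].
#' @param n integration grid size.
#' @return area in mm^2 of the top-down silhouette.
#' @export
silhouette_area <- function(spec, n = 20001) {
  u <- seq(0, spec$length, length.out = n)
  sum(2 * pod_radius(spec, u)) * spec$length / (n - 1)
}

#' Synthetic scan-rig calibration
#'
#' The fixed virtual rig used by the scene generator: camera 500 mm above
#' the table looking straight down (extrinsic rotation `diag(1, -1, -1)`),
#' 2000 px focal lengths, a 64 x 700 sensor region of interest, and a
#' vertical laser sheet offset `plane_offset` mm from the camera nadir
#' (`Yc + plane_offset = 0` in the camera frame); the triangulation baseline
#' is that lateral offset. Guide speed 0.1 mm/s with one frame per second.
#'
#' @param speed guide speed (mm/s).
#' @param frame_interval seconds between frames.
#' @param plane_offset lateral offset of the laser sheet (mm).
#' @param camera_height camera standoff above the table (mm).
#' @param image_size `c(rows, cols)` of the sensor ROI.
#' @param fx,fy,u0,v0 intrinsics (pixels); `v0` lies outside the ROI, which
#'   models a cropped sensor readout.
#' @return A [calibration_set()] with attribute `image_size`.
#' @export
synthetic_calibration <- function(speed = 0.1, frame_interval = 1,
                                  plane_offset = 55, camera_height = 500,
                                  image_size = c(64, 700),
                                  fx = 2000, fy = 2000, u0 = 350, v0 = 260) {
  calib <- calibration_set(
    intrinsics = camera_intrinsics(fx, fy, u0, v0),
    plane = light_plane(0, 1, 0, plane_offset),
    extrinsics = extrinsics(diag(c(1, -1, -1)), c(0, 0, camera_height)),
    speed = speed, frame_interval = frame_interval, guide_axis = c(0, 1, 0))
  attr(calib, "image_size") <- image_size
  attr(calib, "camera_height") <- camera_height
  attr(calib, "plane_offset") <- plane_offset
  calib
}

#' Simulate a structured-light scan of a pod scene
#'
#' Renders the stripe-frame stack a line-laser rig would capture while the
#' guide carries the scene past the fixed laser sheet. Per frame, the sheet
#' cuts the scene at `y = plane_offset + speed * t` (scene coordinates); the
#' visible intersection curve (per camera column, the surface point nearest
#' the camera, which reproduces mutual occlusion) is projected through the
#' pinhole model and drawn as a Gaussian-profile stripe. `noise_px` jitters
#' each column's stripe center vertically (standard deviation in pixels).
#'
#' @param pods list of [pod_spec()] (may be empty for a bare table).
#' @param table_z table elevation (mm) or `NA` for no table.
#' @param calib a [synthetic_calibration()].
#' @param n_frames frame count; default covers the pod bounding box plus a
#'   margin.
#' @param noise_px stripe-center jitter (pixels).
#' @param seed RNG seed.
#' @param margin scan margin beyond the pod extent (mm).
#' @param x_step sampling step along the stripe (mm).
#' @param table_halfwidth half-width of the illuminated table strip beyond
#'   the pod extent (mm).
#' @return List with `frames` (list of [stripe_frame()]) and `truth`:
#'   `cloud` (ideal [pod_cloud()] with pod labels, 0 = table), `column_pod`
#'   (per frame, named integer vector of pod ids per stripe column), `pods`,
#'   `calib`.
#' @export
simulate_scan <- function(pods, table_z = 0, calib = synthetic_calibration(),
                          n_frames = NULL, noise_px = 0, seed = 1,
                          margin = 2, x_step = 0.05, table_halfwidth = 15) {
  imsz <- attr(calib, "image_size")
  if (is.null(imsz)) stop("calib must carry an image_size attribute")
  nr <- imsz[1]; nc <- imsz[2]
  H <- attr(calib, "camera_height")
  y0 <- attr(calib, "plane_offset")
  fx <- calib$intrinsics$fx; fy <- calib$intrinsics$fy
  u0 <- calib$intrinsics$u0; v0 <- calib$intrinsics$v0
  spd <- calib$speed; dt <- calib$frame_interval

  if (length(pods)) {
    ctr <- vapply(pods, function(p) p$position, numeric(2))
    rad <- vapply(pods, function(p) p$length / 2 + max(p$r1, p$r2), numeric(1))
    xlo <- min(ctr[1, ] - rad) - table_halfwidth
    xhi <- max(ctr[1, ] + rad) + table_halfwidth
    ylo <- min(ctr[2, ] - rad) - margin
    yhi <- max(ctr[2, ] + rad) + margin
  } else {
    xlo <- -30; xhi <- 30; ylo <- y0; yhi <- y0 + 5
  }
  if (is.null(n_frames))
    n_frames <- ceiling((yhi - ylo) / (spd * dt)) + 1L
  t0 <- max(0, floor((ylo - y0) / spd / dt)) * dt
  ts <- t0 + (seq_len(n_frames) - 1) * dt

  xs <- seq(xlo, xhi, by = x_step)
  sigma <- 1.2
  win <- -8:8
  gauss <- function(dv) 200 * exp(-dv^2 / (2 * sigma^2))

  frames <- vector("list", n_frames)
  column_pod <- vector("list", n_frames)
  ideal <- vector("list", n_frames)
  any_lit <- FALSE

  with_seed(seed, for (j in seq_len(n_frames)) {
    ycut <- y0 + spd * ts[j]
    surf <- if (length(pods)) scene_surface(pods, xs, rep(ycut, length(xs)))
            else list(z = rep(-Inf, length(xs)), id = integer(length(xs)))
    z <- surf$z; id <- surf$id
    if (!is.na(table_z)) {
      off <- z == -Inf
      z[off] <- table_z
      id[off] <- 0L
    }
    valid <- is.finite(z)
    img <- matrix(0, nr, nc)
    if (any(valid)) {
      xv <- xs[valid]; zv <- z[valid]; idv <- id[valid]
      zc <- H - zv
      uu <- fx * xv / zc + u0
      vv <- v0 - fy * y0 / zc
      cs <- column_samples(uu, vv, zc, idv, nc)
      if (nrow(cs)) {
        any_lit <- TRUE
        vn <- cs[, "v"]
        if (noise_px > 0) vn <- vn + stats::rnorm(length(vn), 0, noise_px)
        rows0 <- round(vn)
        rowmat <- outer(win, rows0, "+")
        valmat <- gauss(sweep(rowmat, 2, vn))
        ok <- rowmat >= 0 & rowmat <= nr - 1
        colmat <- matrix(rep(cs[, "col"], each = length(win)), nrow = length(win))
        img[cbind(rowmat[ok] + 1, colmat[ok] + 1)] <- valmat[ok]
        column_pod[[j]] <- stats::setNames(as.integer(cs[, "pod"]), cs[, "col"])
        # true scene-frame coordinates of the per-column stripe points
        zi <- H - cs[, "zc"]
        xw <- (cs[, "col"] - u0) * cs[, "zc"] / fx
        ideal[[j]] <- cbind(xw, ycut, zi, cs[, "pod"], j)
      }
    }
    frames[[j]] <- stripe_frame(img, timestamp = ts[j], index = j)
  })
  if (!any_lit) warning("light plane never intersects the scene; all frames dark")

  ideal <- do.call(rbind, ideal[!vapply(ideal, is.null, logical(1))])
  truth <- list(
    cloud = if (is.null(ideal)) pod_cloud(matrix(numeric(0), 0, 3))
            else pod_cloud(ideal[, 1:3, drop = FALSE],
                           labels = as.integer(ideal[, 4]),
                           frame_ids = as.integer(ideal[, 5])),
    column_pod = column_pod,
    pods = pods, calib = calib, timestamps = ts)
  list(frames = frames, truth = truth)
}

# per integer camera column: the stripe sample nearest the camera.
# uu/vv/zc are the continuous projections of the stripe samples in order of
# increasing x; folds (several x projecting into one column) are resolved by
# minimal camera depth, which is exactly the occlusion rule of the rig.
column_samples <- function(uu, vv, zc, idv, nc) {
  empty <- matrix(numeric(0), 0, 4,
                  dimnames = list(NULL, c("col", "v", "zc", "pod")))
  n <- length(uu)
  if (n < 2) return(empty)
  a <- uu[-n]; b <- uu[-1]
  clo <- ceiling(pmin(a, b)); chi <- floor(pmax(a, b))
  keep <- which(chi >= clo & clo >= 0 & chi <= nc - 1 &
                  abs(b - a) > .Machine$double.eps)
  if (!length(keep)) return(empty)
  single <- keep[clo[keep] == chi[keep]]
  multi <- keep[clo[keep] < chi[keep]]
  lerp <- function(i, cc) {
    tt <- (cc - uu[i]) / (uu[i + 1] - uu[i])
    vz <- vv[i] + tt * (vv[i + 1] - vv[i])
    zz <- zc[i] + tt * (zc[i + 1] - zc[i])
    pid <- ifelse(tt < 0.5, idv[i], idv[i + 1])
    cbind(col = cc, v = vz, zc = zz, pod = pid)
  }
  out <- lerp(single, clo[single])
  for (i in multi)
    out <- rbind(out, lerp(rep(i, chi[i] - clo[i] + 1), clo[i]:chi[i]))
  # occlusion: keep the minimal camera depth per column
  o <- order(out[, "col"], out[, "zc"])
  out <- out[o, , drop = FALSE]
  out[!duplicated(out[, "col"]), , drop = FALSE]
}

#' Render a top-down grayscale scene with ground-truth masks
#'
#' Orthographic view of the pods on a dark table: foreground intensity is a
#' Lambertian-style shading of the upper-surface normal scaled linearly by
#' `illumination` (then clipped to `[0, 1]`), plus additive Gaussian pixel
#' noise. Per-pod instance masks come from the same height fields that shade
#' the image, so they align with the silhouettes exactly and are disjoint
#' (each pixel belongs to the highest surface). Pods interpenetrating deeper
#' than `interpen_tol` raise an error.
#'
#' @param pods list of [pod_spec()].
#' @param mm_per_pixel pixel size (mm).
#' @param illumination linear foreground intensity factor.
#' @param seed RNG seed for the pixel noise.
#' @param pad_mm margin around the pod bounding box (mm).
#' @param noise_sd additive noise standard deviation (intensity units).
#' @param interpen_tol maximum allowed 3D interpenetration depth (mm).
#' @param extent optional `c(xlo, xhi, ylo, yhi)` overriding the automatic
#'   extent.
#' @return List with `image` (rows x cols, values in `[0, 1]`, row = +Y),
#'   `masks` (list of logical matrices, one per pod), `origin` (mm of pixel
#'   (1,1) center), `mm_per_pixel`, `poses` (data.frame of true positions).
#' @export
render_topdown <- function(pods, mm_per_pixel = 0.2, illumination = 1,
                           seed = 1, pad_mm = 6, noise_sd = 0.015,
                           interpen_tol = 1.0, extent = NULL) {
  if (!(mm_per_pixel > 0)) stop("mm_per_pixel must be positive")
  if (is.null(extent)) {
    if (length(pods)) {
      ctr <- vapply(pods, function(p) p$position, numeric(2))
      rad <- vapply(pods, function(p) p$length / 2 + max(p$r1, p$r2), numeric(1))
      extent <- c(min(ctr[1, ] - rad) - pad_mm, max(ctr[1, ] + rad) + pad_mm,
                  min(ctr[2, ] - rad) - pad_mm, max(ctr[2, ] + rad) + pad_mm)
    } else extent <- c(-10, 10, -10, 10)
  }
  xs <- seq(extent[1], extent[2], by = mm_per_pixel)
  ys <- seq(extent[3], extent[4], by = mm_per_pixel)
  nc <- length(xs); nr <- length(ys)
  gx <- rep(xs, each = nr)   # column-major over (row=y, col=x)
  gy <- rep(ys, times = nc)

  check_interpenetration(pods, interpen_tol)

  surf <- scene_surface(pods, gx, gy)
  idm <- matrix(surf$id, nr, nc)
  nzm <- matrix(surf$nz, nr, nc)
  img <- matrix(0.12, nr, nc)
  fg <- idm > 0
  img[fg] <- illumination * (0.40 + 0.55 * nzm[fg]^1.5)
  with_seed(seed, {
    img <- img + matrix(stats::rnorm(nr * nc, 0, noise_sd), nr, nc)
  })
  img <- pmin(pmax(img, 0), 1)
  masks <- lapply(seq_along(pods), function(i) idm == i)
  poses <- if (length(pods))
    data.frame(pod = seq_along(pods),
               x = vapply(pods, function(p) p$position[1], numeric(1)),
               y = vapply(pods, function(p) p$position[2], numeric(1)),
               yaw = vapply(pods, function(p) p$yaw, numeric(1)))
    else data.frame(pod = integer(0), x = numeric(0), y = numeric(0),
                    yaw = numeric(0))
  list(image = img, masks = masks, origin = c(xs[1], ys[1]),
       mm_per_pixel = mm_per_pixel, poses = poses, pod_id = idm)
}

check_interpenetration <- function(pods, tol, step = 0.25) {
  if (length(pods) < 2) return(invisible(TRUE))
  for (i in seq_len(length(pods) - 1)) for (j in (i + 1):length(pods)) {
    a <- pods[[i]]; b <- pods[[j]]
    lo <- pmax(a$position - a$length, b$position - b$length)
    hi <- pmin(a$position + a$length, b$position + b$length)
    if (any(hi < lo)) next
    xs <- seq(lo[1], hi[1], by = step); ys <- seq(lo[2], hi[2], by = step)
    gx <- rep(xs, each = length(ys)); gy <- rep(ys, times = length(xs))
    ha <- pod_height(a, gx, gy); hb <- pod_height(b, gx, gy)
    both <- which(ha$inside & hb$inside)
    if (!length(both)) next
    # true penetration: a point inside both solids, by its smaller interior depth
    depth <- 0
    for (p in both) {
      zlo <- max(ha$zlow[p], hb$zlow[p]); zhi <- min(ha$z[p], hb$z[p])
      if (zhi <= zlo) next
      zs <- seq(zlo, zhi, length.out = 9)
      da <- radial_depth(a, rep(gx[p], 9), rep(gy[p], 9), zs)
      db <- radial_depth(b, rep(gx[p], 9), rep(gy[p], 9), zs)
      depth <- max(depth, max(pmin(da, db)))
    }
    if (depth > tol)
      stop(sprintf("pods %d and %d interpenetrate by %.2f mm (tol %.2f)",
                   i, j, depth, tol))
  }
  invisible(TRUE)
}

# interior depth of a world point inside a pod solid (positive inside)
radial_depth <- function(spec, x, y, z) {
  loc <- pod_local(spec, x, y)
  rho <- pod_radius(spec, loc$u)
  rho - sqrt(loc$w^2 + (z - spec$axis_height)^2)
}

#' Compose an adherent scene from morphologies
#'
#' Places one pod per requested morphology in a row along +X, axes roughly
#' along +Y, with alternating small yaw and lateral stagger, each pod pushed
#' against the previous one until their silhouettes overlap by `contact` mm
#' (touching pods whose 2D silhouettes merge into one component). Per-pod
#' sizes are jittered a few percent for diversity.
#'
#' @param morphologies character vector of morphology names (length 2-5).
#' @param seed RNG seed.
#' @param contact silhouette overlap depth between neighbors (mm).
#' @param y_center common y position of the row (mm).
#' @param size_jitter relative lobe-size jitter.
#' @return List of [pod_spec()].
#' @export
make_scene <- function(morphologies, seed = 1, contact = 0.25,
                       y_center = 85, size_jitter = 0.06) {
  stopifnot(length(morphologies) >= 1)
  with_seed(seed, {
    pods <- list()
    x_at <- 0
    for (i in seq_along(morphologies)) {
      base <- pod_morphologies()[[morphologies[i]]]
      if (is.null(base)) stop("unknown morphology: ", morphologies[i])
      jit <- function(v) v * (1 + stats::runif(1, -size_jitter, size_jitter))
      yaw <- (pi / 2) + stats::runif(1, -0.22, 0.22)   # axes roughly along +Y
      stag <- stats::runif(1, -3, 3)
      spec <- pod_spec(morphologies[i], r1 = jit(base$r1), r2 = jit(base$r2),
                       sep = jit(base$sep), waist = base$waist,
                       position = c(x_at, y_center + stag), yaw = yaw)
      if (i > 1) {
        gap <- silhouette_gap(pods[[i - 1]], spec)
        spec$position[1] <- spec$position[1] - gap - contact
      }
      pods[[i]] <- spec
      x_at <- spec$position[1] + max(spec$r1, spec$r2) + spec$length / 2 + 30
    }
    pods
  })
}

# smallest +X shift that would bring pod b's silhouette into contact with
# pod a's: minimal horizontal clearance measured row-wise on a fine grid
silhouette_gap <- function(a, b, step = 0.1) {
  ys <- seq(min(a$position[2], b$position[2]) - 30,
            max(a$position[2], b$position[2]) + 30, by = step)
  xa <- seq(a$position[1] - a$length, a$position[1] + a$length, by = step)
  xb <- seq(b$position[1] - b$length, b$position[1] + b$length, by = step)
  right_a <- rep(-Inf, length(ys))
  left_b <- rep(Inf, length(ys))
  ha <- pod_height(a, rep(xa, each = length(ys)), rep(ys, times = length(xa)))
  hb <- pod_height(b, rep(xb, each = length(ys)), rep(ys, times = length(xb)))
  ia <- matrix(ha$inside, length(ys), length(xa))
  ib <- matrix(hb$inside, length(ys), length(xb))
  for (r in seq_along(ys)) {
    if (any(ia[r, ])) right_a[r] <- max(xa[ia[r, ]])
    if (any(ib[r, ])) left_b[r] <- min(xb[ib[r, ]])
  }
  both <- is.finite(right_a) & is.finite(left_b)
  if (!any(both)) stop("pods do not overlap in y; cannot make them adherent")
  min(left_b[both] - right_a[both])
}

#' Ideal visible-surface cloud of an adherent scene
#'
#' Regular-grid sampling of the upper envelope the rig can see (table
#' excluded), with ground-truth pod labels. This is the idealized, noise-free
#' stand-in for a reconstructed scan used as the region-growing oracle.
#'
#' @param pods list of [pod_spec()].
#' @param spacing grid spacing (mm).
#' @return A [pod_cloud()] with truth labels (pod index, 1-based).
#' @export
ideal_adherent_cloud <- function(pods, spacing = 0.3) {
  ctr <- vapply(pods, function(p) p$position, numeric(2))
  rad <- vapply(pods, function(p) p$length / 2 + max(p$r1, p$r2), numeric(1))
  xs <- seq(min(ctr[1, ] - rad), max(ctr[1, ] + rad), by = spacing)
  ys <- seq(min(ctr[2, ] - rad), max(ctr[2, ] + rad), by = spacing)
  gx <- rep(xs, each = length(ys)); gy <- rep(ys, times = length(xs))
  surf <- scene_surface(pods, gx, gy)
  keep <- surf$id > 0
  pod_cloud(cbind(gx[keep], gy[keep], surf$z[keep]),
            labels = surf$id[keep])
}

# run code under a seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}
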