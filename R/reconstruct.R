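#' Laser-stripe frame
#'
#' One grayscale stripe image together with its acquisition time. Image
#' matrices are indexed `[row, column]`; intensities may be on any
#' non-negative scale.
#'
#' @param image numeric matrix (rows x columns) of intensities.
#' @param timestamp seconds since scan start (>= 0).
#' @param index frame ordinal (integer).
#' @return An object of class `stripe_frame`.
#' @export
stripe_frame <- function(image, timestamp, index = NA_integer_) {
  image <- as.matrix(image)
  storage.mode(image) <- "double"
  if (length(image) == 0) stop("frame image is empty")
  if (!is.finite(timestamp) || timestamp < 0) stop("timestamp must be >= 0")
  structure(list(image = image, timestamp = as.numeric(timestamp),
                 index = as.integer(index)),
            class = "stripe_frame")
}

#' Extract the sub-pixel stripe centerline from one frame
#'
#' Per image column, the centerline row is the intensity-weighted centroid
#' (gray-gravity center) of the pixels whose intensity exceeds the threshold.
#' Columns with no above-threshold pixel contribute nothing. Coordinates are
#' 0-based `(u, v) = (column, row)` with pixel centers at integers.
#'
#' @param frame a [stripe_frame()] or numeric image matrix.
#' @param intensity_threshold pixels strictly above this value enter the
#'   centroid; must lie in `[0, max(image)]`.
#' @return Numeric matrix with columns `u`, `v`; zero rows when nothing is
#'   above threshold.
#' @export
extract_stripe_centerline <- function(frame, intensity_threshold = 30) {
  img <- if (inherits(frame, "stripe_frame")) frame$image else as.matrix(frame)
  if (length(img) == 0) stop("frame image is empty")
  if (intensity_threshold < 0) stop("threshold must be >= 0")
  mask <- img > intensity_threshold
  hit <- which(colSums(mask) > 0)
  if (length(hit) == 0)
    return(matrix(numeric(0), 0, 2, dimnames = list(NULL, c("u", "v"))))
  w <- img * mask
  rows0 <- seq_len(nrow(img)) - 1     # 0-based row coordinates
  v <- colSums(w[, hit, drop = FALSE] * rows0) / colSums(w[, hit, drop = FALSE])
  cbind(u = hit - 1, v = v)
}

#' Triangulate pixels against the light plane
#'
#' Intersects each pixel's viewing ray with the calibrated laser plane. With
#' ray direction `((u-u0)/fx, (v-v0)/fy, 1)` the depth has the closed form
#' `Zc = -d / (a*(u-u0)/fx + b*(v-v0)/fy + c)`; the returned camera-frame
#' point reprojects exactly to `(u, v)` and satisfies the plane equation.
#'
#' @param pixels numeric vector `c(u, v)` or N x 2 matrix of pixel
#'   coordinates.
#' @param intrinsics a [camera_intrinsics()].
#' @param plane a [light_plane()].
#' @return N x 3 matrix of camera-frame points `(Xc, Yc, Zc)`.
#' @export
backproject_to_plane <- function(pixels, intrinsics, plane) {
  if (is.null(dim(pixels))) pixels <- matrix(pixels, ncol = 2, byrow = TRUE)
  pixels <- as.matrix(pixels)
  stopifnot(ncol(pixels) == 2)
  rx <- (pixels[, 1] - intrinsics$u0) / intrinsics$fx
  ry <- (pixels[, 2] - intrinsics$v0) / intrinsics$fy
  denom <- plane$a * rx + plane$b * ry + plane$c
  if (any(abs(denom) < 1e-12))
    stop("viewing ray is parallel to the light plane")
  zc <- -plane$d / denom
  cbind(Xc = rx * zc, Yc = ry * zc, Zc = zc)
}

#' Project camera-frame points to pixels
#'
#' The forward pinhole map, used for round-trip checks of
#' [backproject_to_plane()].
#'
#' @param points N x 3 camera-frame points.
#' @param intrinsics a [camera_intrinsics()].
#' @return N x 2 matrix of `(u, v)` pixel coordinates.
#' @export
project_pixels <- function(points, intrinsics) {
  points <- as_xyz_matrix(points)
  if (any(points[, 3] == 0)) stop("cannot project points with Zc = 0")
  cbind(u = intrinsics$fx * points[, 1] / points[, 3] + intrinsics$u0,
        v = intrinsics$fy * points[, 2] / points[, 3] + intrinsics$v0)
}

#' Transform camera-frame points to world coordinates
#'
#' Inverts the rigid extrinsic map `camera = R %*% world + T` in closed form,
#' `world = t(R) %*% (camera - T)`.
#'
#' @param points N x 3 camera-frame points (or a length-3 vector).
#' @param extr a [extrinsics()].
#' @return N x 3 matrix of world-frame points.
#' @export
camera_to_world <- function(points, extr) {
  points <- as_xyz_matrix(points)
  out <- sweep(points, 2, extr$T) %*% extr$R  # (p - T) %*% R == t(R'(p - T))'
  colnames(out) <- c("Xw", "Yw", "Zw")
  out
}

#' Reconstruct and splice a stripe-frame stack into a world-frame cloud
#'
#' For every frame: extract the stripe centerline, triangulate it against the
#' light plane, transform to world coordinates, then offset by the guide
#' displacement `d = speed * timestamp` along the calibrated guide axis.
#'
#' @param frames list of [stripe_frame()] objects with strictly increasing
#'   timestamps.
#' @param calib a [calibration_set()].
#' @param intensity_threshold centerline threshold, see
#'   [extract_stripe_centerline()].
#' @return A [pod_cloud()] with `frame_ids` recording each point's source
#'   frame; empty (with a warning) when no frame contains a stripe.
#' @export
assemble_cloud <- function(frames, calib, intensity_threshold = 30) {
  stopifnot(length(frames) >= 1)
  ts <- vapply(frames, function(f) f$timestamp, numeric(1))
  if (any(diff(ts) <= 0))
    stop("frame timestamps must be strictly increasing")
  per <- vector("list", length(frames))
  ids <- vector("list", length(frames))
  for (i in seq_along(frames)) {
    cl <- extract_stripe_centerline(frames[[i]], intensity_threshold)
    if (nrow(cl) == 0) next
    cam <- backproject_to_plane(cl, calib$intrinsics, calib$plane)
    wld <- camera_to_world(cam, calib$extrinsics)
    d <- calib$speed * frames[[i]]$timestamp
    wld <- wld + matrix(d * calib$guide_axis, nrow(wld), 3, byrow = TRUE)
    per[[i]] <- wld
    idx <- frames[[i]]$index
    ids[[i]] <- rep(if (is.na(idx)) i else idx, nrow(wld))
  }
  keep <- !vapply(per, is.null, logical(1))
  if (!any(keep)) {
    warning("no stripe centerline found in any frame; returning empty cloud")
    return(pod_cloud(matrix(numeric(0), 0, 3)))
  }
  pod_cloud(do.call(rbind, per[keep]),
            frame_ids = unlist(ids[keep]))
}

#' Read a directory of stripe frames
#'
#' Loads PNG or TIFF images named `frame_00000.png` (any zero-padded ordinal)
#' in lexical order. Timestamps default to `index * frame_interval`; a sidecar
#' CSV with columns `index,timestamp` overrides them.
#'
#' @param dir directory containing the frames.
#' @param frame_interval seconds between frames (used when no sidecar exists).
#' @param timestamps_csv optional CSV path with columns `index`, `timestamp`.
#' @param scale multiply intensities by this factor (PNG readers return
#'   values in `[0, 1]`; the default rescales to 0-255).
#' @return List of [stripe_frame()] objects.
#' @export
read_frames <- function(dir, frame_interval = 1, timestamps_csv = NULL,
                        scale = 255) {
  files <- sort(list.files(dir, pattern = "\\.(png|tif|tiff)$",
                           ignore.case = TRUE, full.names = TRUE))
  if (length(files) == 0) stop("no PNG/TIFF frames found in ", dir)
  tmap <- NULL
  if (!is.null(timestamps_csv)) {
    tdf <- utils::read.csv(timestamps_csv)
    tmap <- stats::setNames(tdf$timestamp, tdf$index)
  }
  lapply(seq_along(files), function(i) {
    f <- files[[i]]
    img <- if (grepl("\\.png$", f, ignore.case = TRUE)) png::readPNG(f)
           else tiff::readTIFF(f)
    if (length(dim(img)) == 3) img <- img[, , 1]
    idx <- i - 1L
    num <- regmatches(basename(f), regexpr("[0-9]+", basename(f)))
    if (length(num) == 1) idx <- as.integer(num)
    ts <- if (!is.null(tmap) && !is.na(tmap[as.character(idx)]))
      unname(tmap[as.character(idx)]) else idx * frame_interval
    stripe_frame(img * scale, timestamp = ts, index = idx)
  })
}
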