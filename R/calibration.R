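#' Camera intrinsics
#'
#' Pinhole intrinsics of the stripe camera: `fx`, `fy` are the focal length
#' divided by the pixel pitch along the image X and Y axes (pixels), and
#' `(u0, v0)` is the principal point (pixels). The pixel convention throughout
#' the package is `(u, v) = (column, row)`, 0-based, with pixel centers at
#' integer coordinates.
#'
#' @param fx,fy focal lengths in pixels (must be positive).
#' @param u0,v0 principal point in pixels.
#' @return An object of class `camera_intrinsics`.
#' @export
camera_intrinsics <- function(fx, fy, u0, v0) {
  stopifnot(is.finite(fx), is.finite(fy), is.finite(u0), is.finite(v0))
  if (fx <= 0 || fy <= 0) stop("fx and fy must be positive")
  structure(list(fx = fx, fy = fy, u0 = u0, v0 = v0),
            class = "camera_intrinsics")
}

#' Laser light-plane coefficients
#'
#' The laser sheet expressed in the camera frame as
#' `a*Xc + b*Yc + c*Zc + d = 0`.
#'
#' @param a,b,c,d plane coefficients; `(a, b, c)` must not all be zero.
#' @return An object of class `light_plane`.
#' @export
light_plane <- function(a, b, c, d) {
  stopifnot(is.finite(a), is.finite(b), is.finite(c), is.finite(d))
  if (a == 0 && b == 0 && c == 0) stop("(a, b, c) must not all be zero")
  structure(list(a = a, b = b, c = c, d = d), class = "light_plane")
}

#' Camera extrinsics
#'
#' Rotation `R` (3x3) and translation `T` (mm) mapping world coordinates into
#' the camera frame, `camera = R %*% world + T`. Rotation matrices supplied by
#' physical calibration are often orthonormal only to ~1e-3, so violations of
#' `R'R = I` or `det(R) = 1` beyond 1e-6 produce a warning, not an error.
#'
#' @param R 3x3 rotation matrix.
#' @param T length-3 translation vector (mm).
#' @return An object of class `camera_extrinsics`.
#' @export
extrinsics <- function(R, T) {
  R <- matrix(as.numeric(R), 3, 3)
  T <- as.numeric(T)
  stopifnot(length(T) == 3, all(is.finite(R)), all(is.finite(T)))
  ortho_err <- max(abs(crossprod(R) - diag(3)))
  det_err <- abs(det(R) - 1)
  if (ortho_err > 1e-6 || det_err > 1e-6)
    warning(sprintf(paste0("extrinsic rotation is not orthonormal ",
                           "(|R'R - I| = %.2e, |det R - 1| = %.2e)"),
                    ortho_err, det_err))
  structure(list(R = R, T = T), class = "camera_extrinsics")
}

#' Full calibration set for a structured-light scan
#'
#' Bundles everything triangulation and splicing need: camera intrinsics, the
#' light-plane equation, extrinsics, the guide velocity `speed` (mm/s) and the
#' inter-frame interval (s). Per-frame displacement along the guide axis is
#' `d = speed * timestamp`.
#'
#' @param intrinsics a [camera_intrinsics()].
#' @param plane a [light_plane()].
#' @param extrinsics a [extrinsics()].
#' @param speed guide velocity in mm/s (>= 0).
#' @param frame_interval seconds between consecutive frames (> 0).
#' @param guide_axis world-frame unit direction of the guide motion; the
#'   default `+Y` matches the synthetic rig.
#' @return An object of class `calibration_set`.
#' @export
calibration_set <- function(intrinsics, plane, extrinsics, speed,
                            frame_interval, guide_axis = c(0, 1, 0)) {
  stopifnot(inherits(intrinsics, "camera_intrinsics"),
            inherits(plane, "light_plane"),
            inherits(extrinsics, "camera_extrinsics"))
  if (!is.finite(speed) || speed < 0) stop("speed must be >= 0")
  if (!is.finite(frame_interval) || frame_interval <= 0)
    stop("frame_interval must be > 0")
  guide_axis <- as.numeric(guide_axis)
  stopifnot(length(guide_axis) == 3)
  nrm <- sqrt(sum(guide_axis^2))
  if (nrm == 0) stop("guide_axis must be nonzero")
  structure(list(intrinsics = intrinsics, plane = plane,
                 extrinsics = extrinsics, speed = speed,
                 frame_interval = frame_interval,
                 guide_axis = guide_axis / nrm),
            class = "calibration_set")
}

#' @export
print.calibration_set <- function(x, ...) {
  cat(sprintf("calibration_set: fx=%.4g fy=%.4g u0=%.4g v0=%.4g\n",
              x$intrinsics$fx, x$intrinsics$fy, x$intrinsics$u0, x$intrinsics$v0))
  cat(sprintf("  plane: %.6g Xc + %.6g Yc + %.6g Zc + %.6g = 0\n",
              x$plane$a, x$plane$b, x$plane$c, x$plane$d))
  cat(sprintf("  speed: %.4g mm/s, frame interval: %.4g s, guide axis: (%g, %g, %g)\n",
              x$speed, x$frame_interval,
              x$guide_axis[1], x$guide_axis[2], x$guide_axis[3]))
  invisible(x)
}

#' Read a calibration file (YAML or JSON)
#'
#' Expects keys `intrinsics{fx,fy,u0,v0}`, `plane{a,b,c,d}`,
#' `extrinsics{R (row-major 9), T (3)}`, `speed`, `frame_interval` and
#' optionally `guide_axis`.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return A [calibration_set()].
#' @export
read_calibration <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
         else if (ext == "json") jsonlite::fromJSON(path)
         else stop("unsupported calibration format: ", ext)
  need <- c("intrinsics", "plane", "extrinsics", "speed", "frame_interval")
  missing <- setdiff(need, names(raw))
  if (length(missing)) stop("calibration file missing: ",
                            paste(missing, collapse = ", "))
  calibration_set(
    intrinsics = with(raw$intrinsics, camera_intrinsics(fx, fy, u0, v0)),
    plane = with(raw$plane, light_plane(a, b, c, d)),
    extrinsics = extrinsics(matrix(as.numeric(raw$extrinsics$R), 3, 3,
                                   byrow = TRUE),
                            as.numeric(raw$extrinsics$T)),
    speed = raw$speed,
    frame_interval = raw$frame_interval,
    guide_axis = if (is.null(raw$guide_axis)) c(0, 1, 0) else raw$guide_axis)
}

#' Write a calibration set (YAML or JSON)
#' @param calib a [calibration_set()].
#' @param path output `.yaml`/`.yml` or `.json` path.
#' @return `path`, invisibly.
#' @export
write_calibration <- function(calib, path) {
  obj <- list(
    intrinsics = calib$intrinsics[c("fx", "fy", "u0", "v0")],
    plane = calib$plane[c("a", "b", "c", "d")],
    extrinsics = list(R = as.numeric(t(calib$extrinsics$R)),
                      T = as.numeric(calib$extrinsics$T)),
    speed = calib$speed,
    frame_interval = calib$frame_interval,
    guide_axis = calib$guide_axis)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) yaml::write_yaml(obj, path)
  else if (ext == "json") jsonlite::write_json(obj, path, auto_unbox = TRUE,
                                               digits = NA)
  else stop("unsupported calibration format: ", ext)
  invisible(path)
}
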