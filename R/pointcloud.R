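#' Point cloud container
#'
#' A `pod_cloud` holds N world-frame points (mm) with optional per-point
#' surface attributes filled in by later pipeline stages: unit normals,
#' surface-variation curvatures in `[0, 1/3]`, integer region labels
#' (`-1` = unassigned/residual) and the index of the stripe frame each point
#' came from.
#'
#' @param points numeric N x 3 matrix of coordinates (mm).
#' @param normals optional N x 3 matrix of unit normals.
#' @param curvatures optional numeric vector of curvatures in `[0, 1/3]`.
#' @param labels optional integer vector of region ids (>= -1).
#' @param frame_ids optional integer vector of source frame ordinals.
#' @return An object of class `pod_cloud`.
#' @export
pod_cloud <- function(points, normals = NULL, curvatures = NULL,
                      labels = NULL, frame_ids = NULL) {
  points <- as_xyz_matrix(points)
  n <- nrow(points)
  if (!is.null(normals)) {
    normals <- as_xyz_matrix(normals)
    stopifnot(nrow(normals) == n)
    nrm <- sqrt(rowSums(normals^2))
    if (any(abs(nrm - 1) > 1e-8))
      stop("normals must have unit norm (within 1e-8)")
  }
  if (!is.null(curvatures)) {
    curvatures <- as.numeric(curvatures)
    stopifnot(length(curvatures) == n)
    if (any(curvatures < -1e-12 | curvatures > 1 / 3 + 1e-12))
      stop("curvatures must lie in [0, 1/3]")
  }
  if (!is.null(labels)) {
    labels <- as.integer(labels)
    stopifnot(length(labels) == n)
    if (any(labels < -1L)) stop("labels must be >= -1")
  }
  if (!is.null(frame_ids)) {
    frame_ids <- as.integer(frame_ids)
    stopifnot(length(frame_ids) == n)
  }
  structure(list(points = points, normals = normals, curvatures = curvatures,
                 labels = labels, frame_ids = frame_ids),
            class = "pod_cloud")
}

as_xyz_matrix <- function(x) {
  if (is.null(dim(x)) && length(x) == 3) x <- matrix(x, 1, 3)
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (ncol(x) != 3) stop("expected an N x 3 coordinate matrix")
  if (any(!is.finite(x))) stop("coordinates must be finite")
  dimnames(x) <- NULL
  x
}

#' Number of points in a cloud
#' @param cloud a [pod_cloud()].
#' @return integer point count.
#' @export
cloud_size <- function(cloud) nrow(cloud$points)

#' Subset a point cloud
#'
#' Keeps the selected points together with whatever per-point attributes are
#' present, preserving order.
#'
#' @param cloud a [pod_cloud()].
#' @param idx integer or logical index vector.
#' @return A `pod_cloud` with the selected points.
#' @export
cloud_subset <- function(cloud, idx) {
  pick <- function(x) if (is.null(x)) NULL else x[idx]
  pod_cloud(cloud$points[idx, , drop = FALSE],
            normals = if (is.null(cloud$normals)) NULL else cloud$normals[idx, , drop = FALSE],
            curvatures = pick(cloud$curvatures),
            labels = pick(cloud$labels),
            frame_ids = pick(cloud$frame_ids))
}

#' @export
print.pod_cloud <- function(x, ...) {
  cat(sprintf("pod_cloud: %d points", cloud_size(x)))
  extras <- c(
    if (!is.null(x$normals)) "normals",
    if (!is.null(x$curvatures)) "curvatures",
    if (!is.null(x$labels)) sprintf("labels (%d regions)",
                                    length(setdiff(unique(x$labels), -1L))),
    if (!is.null(x$frame_ids)) "frame ids")
  if (length(extras)) cat(" [", paste(extras, collapse = ", "), "]", sep = "")
  cat("\n")
  if (cloud_size(x) > 0) {
    rng <- apply(x$points, 2, range)
    cat(sprintf("  extent (mm): x [%.2f, %.2f]  y [%.2f, %.2f]  z [%.2f, %.2f]\n",
                rng[1, 1], rng[2, 1], rng[1, 2], rng[2, 2], rng[1, 3], rng[2, 3]))
  }
  invisible(x)
}

#' @export
summary.pod_cloud <- function(object, ...) {
  print(object)
  if (!is.null(object$labels)) {
    tab <- table(object$labels)
    cat("  region sizes:\n")
    print(tab)
  }
  invisible(object)
}

#' Write a point cloud as ASCII PLY
#'
#' Stores `x, y, z` as float properties and, when present, `nx, ny, nz`,
#' `curvature` (floats) and `label` (int).
#'
#' @param cloud a [pod_cloud()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_cloud_ply <- function(cloud, path) {
  n <- cloud_size(cloud)
  props <- c("property float x", "property float y", "property float z")
  cols <- list(cloud$points[, 1], cloud$points[, 2], cloud$points[, 3])
  if (!is.null(cloud$normals)) {
    props <- c(props, "property float nx", "property float ny", "property float nz")
    cols <- c(cols, list(cloud$normals[, 1], cloud$normals[, 2], cloud$normals[, 3]))
  }
  if (!is.null(cloud$curvatures)) {
    props <- c(props, "property float curvature")
    cols <- c(cols, list(cloud$curvatures))
  }
  if (!is.null(cloud$labels)) {
    props <- c(props, "property int label")
    cols <- c(cols, list(cloud$labels))
  }
  header <- c("ply", "format ascii 1.0",
              sprintf("element vertex %d", n), props, "end_header")
  body <- do.call(paste, c(lapply(cols, function(v) format(v, trim = TRUE, digits = 9)),
                           list(sep = " ")))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read an ASCII PLY point cloud
#'
#' Understands the subset of PLY written by [write_cloud_ply()]: an ASCII
#' vertex element with x/y/z and optional nx/ny/nz, curvature and label
#' properties.
#'
#' @param path PLY file path.
#' @return A [pod_cloud()].
#' @export
read_cloud_ply <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3 || trimws(lines[1]) != "ply")
    stop("not a PLY file: ", path)
  end <- match("end_header", trimws(lines))
  if (is.na(end)) stop("PLY header missing end_header")
  header <- trimws(lines[seq_len(end)])
  if (!any(grepl("^format\\s+ascii", header)))
    stop("only ASCII PLY is supported")
  vline <- grep("^element vertex ", header, value = TRUE)
  if (length(vline) != 1) stop("expected exactly one vertex element")
  n <- as.integer(sub("^element vertex ", "", vline))
  pnames <- sub("^property\\s+\\S+\\s+", "", grep("^property ", header, value = TRUE))
  body <- lines[end + seq_len(n)]
  vals <- utils::read.table(text = body, col.names = pnames,
                            colClasses = "numeric")
  need <- c("x", "y", "z")
  if (!all(need %in% pnames)) stop("PLY must contain x, y, z properties")
  pts <- as.matrix(vals[, need])
  normals <- NULL
  if (all(c("nx", "ny", "nz") %in% pnames)) {
    normals <- as.matrix(vals[, c("nx", "ny", "nz")])
    # renormalize: float-precision round trips drift below unit norm
    nrm <- sqrt(rowSums(normals^2))
    ok <- nrm > 0
    normals[ok, ] <- normals[ok, , drop = FALSE] / nrm[ok]
    normals[!ok, ] <- rep(c(0, 0, 1), each = sum(!ok))
  }
  pod_cloud(pts,
            normals = normals,
            curvatures = if ("curvature" %in% pnames) pmin(pmax(vals$curvature, 0), 1 / 3),
            labels = if ("label" %in% pnames) as.integer(vals$label))
}

#' Write a point cloud as CSV (x,y,z plus optional attributes)
#' @param cloud a [pod_cloud()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_cloud_csv <- function(cloud, path) {
  df <- data.frame(x = cloud$points[, 1], y = cloud$points[, 2],
                   z = cloud$points[, 3])
  if (!is.null(cloud$normals)) {
    df$nx <- cloud$normals[, 1]; df$ny <- cloud$normals[, 2]; df$nz <- cloud$normals[, 3]
  }
  if (!is.null(cloud$curvatures)) df$curvature <- cloud$curvatures
  if (!is.null(cloud$labels)) df$label <- cloud$labels
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a CSV point cloud written by [write_cloud_csv()]
#' @param path CSV file path.
#' @return A [pod_cloud()].
#' @export
read_cloud_csv <- function(path) {
  df <- utils::read.csv(path)
  stopifnot(all(c("x", "y", "z") %in% names(df)))
  normals <- NULL
  if (all(c("nx", "ny", "nz") %in% names(df))) {
    normals <- as.matrix(df[, c("nx", "ny", "nz")])
    nrm <- sqrt(rowSums(normals^2))
    normals[nrm > 0, ] <- normals[nrm > 0, , drop = FALSE] / nrm[nrm > 0]
  }
  pod_cloud(as.matrix(df[, c("x", "y", "z")]), normals = normals,
            curvatures = df$curvature, labels = df$label)
}
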