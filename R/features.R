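#' Elevation pre-filter
#'
#' Keeps the points whose world Z lies inside `[zmin, zmax]`, preserving
#' order. Used to strip the table/background before cloud segmentation.
#'
#' @param cloud a [pod_cloud()].
#' @param zmin,zmax elevation window (mm), `zmin < zmax`.
#' @return The filtered [pod_cloud()]; empty with a warning when nothing
#'   survives.
#' @export
elevation_filter <- function(cloud, zmin, zmax) {
  if (!(zmin < zmax)) stop("zmin must be < zmax")
  keep <- cloud$points[, 3] >= zmin & cloud$points[, 3] <= zmax
  if (!any(keep)) {
    warning("elevation filter removed every point")
    return(pod_cloud(matrix(numeric(0), 0, 3)))
  }
  cloud_subset(cloud, keep)
}

#' K-nearest-neighbor graph of a cloud
#'
#' Exact Euclidean k-nearest neighbors of every point (self excluded),
#' computed on a uniform-grid spatial index. Neighbor lists are sorted by
#' increasing distance; exact distance ties are broken by lower point index.
#'
#' @param cloud a [pod_cloud()] (or N x 3 matrix) with N >= 2 points.
#' @param k neighbor count (>= 1); capped at N - 1.
#' @return An object of class `pod_neighbor_graph` with fields `k`,
#'   `neighbor_indices` (N x min(k, N-1), 1-based) and `distances`.
#' @export
build_neighbor_graph <- function(cloud, k) {
  pts <- if (inherits(cloud, "pod_cloud")) cloud$points else as_xyz_matrix(cloud)
  if (k < 1) stop("k must be >= 1")
  if (nrow(pts) < 2) stop("need at least 2 points")
  res <- knn_grid(pts, as.integer(k))
  structure(list(k = min(k, nrow(pts) - 1L),
                 neighbor_indices = res$idx,
                 distances = res$dist,
                 n = nrow(pts)),
            class = "pod_neighbor_graph")
}

#' @export
print.pod_neighbor_graph <- function(x, ...) {
  cat(sprintf("pod_neighbor_graph: %d points, k = %d, median spacing %.4g mm\n",
              x$n, x$k, stats::median(x$distances[, 1])))
  invisible(x)
}

#' Estimate surface normals and surface-variation curvature
#'
#' Fits a local plane (PCA of the neighborhood covariance) through each point
#' and its k neighbors. The normal is the eigenvector of the smallest
#' eigenvalue; the curvature is the surface variation
#' `rho = lambda1 / (lambda1 + lambda2 + lambda3)` with
#' `lambda1 <= lambda2 <= lambda3`, which is 0 on planes and at most 1/3 for
#' isotropic neighborhoods. Normals are sign-flipped toward the viewpoint
#' direction for output consistency (PCA normals have arbitrary sign).
#' All-coincident neighborhoods get curvature 0 and a flagged `(0, 0, 1)`
#' normal.
#'
#' @param cloud a [pod_cloud()].
#' @param graph a [build_neighbor_graph()] built on the same cloud.
#' @param viewpoint unit direction normals should point along (default `+Z`,
#'   the synthetic rig's camera direction).
#' @return The cloud with `normals` and `curvatures` filled; degenerate
#'   neighborhoods are reported in `attr(, "degenerate")`.
#' @export
estimate_normals_curvature <- function(cloud, graph, viewpoint = c(0, 0, 1)) {
  stopifnot(inherits(graph, "pod_neighbor_graph"))
  if (graph$n != cloud_size(cloud))
    stop("neighbor graph was built on a different cloud")
  if (graph$k + 1 < 3)
    stop("each neighborhood needs at least 3 points (k >= 2)")
  res <- normals_curvature_cpp(cloud$points, graph$neighbor_indices)
  normals <- res$normals
  vp <- viewpoint / sqrt(sum(viewpoint^2))
  dots <- as.numeric(normals %*% vp)
  flip <- dots < 0 | (dots == 0 & apply_sign_tiebreak(normals))
  normals[flip, ] <- -normals[flip, , drop = FALSE]
  out <- cloud
  out$normals <- normals
  out$curvatures <- as.numeric(pmin(pmax(res$curvatures, 0), 1 / 3))
  attr(out, "degenerate") <- res$degenerate
  out
}

# deterministic sign for normals orthogonal to the viewpoint: first nonzero
# component must be positive
apply_sign_tiebreak <- function(normals) {
  first_neg <- normals[, 1] < 0 |
    (normals[, 1] == 0 & (normals[, 2] < 0 |
                            (normals[, 2] == 0 & normals[, 3] < 0)))
  first_neg
}

#' Voxel-grid downsampling
#'
#' Replaces the points in each cubic voxel by their centroid. Standard cloud
#' conditioning before feature estimation and region growing: it evens out
#' the strongly anisotropic sampling of a stripe scan (dense along the guide
#' axis, coarse across it). Output order follows the first point seen in each
#' voxel, so the result is deterministic.
#'
#' @param cloud a [pod_cloud()].
#' @param voxel voxel edge length (mm, > 0).
#' @return A [pod_cloud()] of voxel centroids (attributes are dropped).
#' @export
voxel_downsample <- function(cloud, voxel) {
  if (!(voxel > 0)) stop("voxel must be positive")
  pts <- cloud$points
  if (nrow(pts) == 0) return(cloud)
  cellmat <- floor(sweep(pts, 2, apply(pts, 2, min)) / voxel)
  key <- paste(cellmat[, 1], cellmat[, 2], cellmat[, 3])
  grp <- match(key, unique(key))       # 1..G in first-occurrence order
  out <- rowsum(pts, grp) / tabulate(grp)
  pod_cloud(out)
}
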