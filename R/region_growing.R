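#' Region-growing parameters
#'
#' @param k neighbor count used for features and growth (>= 3).
#' @param angle_thresh maximum angle (degrees, in `(0, 90)`) between the
#'   current seed's normal and a neighbor's normal for the neighbor to join
#'   the region. Angles are measured between unoriented normals.
#' @param curv_thresh maximum surface-variation curvature (in `[0, 1/3]`) for
#'   a joined point to be promoted to a seed and expand further.
#' @param min_region minimum point count of an accepted region (>= 1).
#' @return An object of class `growth_params`.
#' @export
growth_params <- function(k = 30, angle_thresh = 15, curv_thresh = 0.05,
                          min_region = 100) {
  if (k < 3) stop("k must be >= 3")
  if (!(angle_thresh > 0 && angle_thresh < 90))
    stop("angle_thresh must be in (0, 90) degrees")
  if (curv_thresh < 0 || curv_thresh > 1 / 3)
    stop("curv_thresh must be in [0, 1/3]")
  if (min_region < 1) stop("min_region must be >= 1")
  structure(list(k = as.integer(k), angle_thresh = angle_thresh,
                 curv_thresh = curv_thresh, min_region = as.integer(min_region)),
            class = "growth_params")
}

#' Curvature-seeded region growing
#'
#' Splits a featured cloud into smooth regions (individual pods). The point
#' of globally lowest curvature seeds a region; its neighbors join when the
#' angle between their normal and the current seed's normal (unoriented,
#' `acos(|n1 . n2|)`) is below `angle_thresh`; a joined point is promoted to
#' a seed itself only when its curvature is below `curv_thresh` (two-tier
#' rule). Growth repeats from the next lowest-curvature unassigned point
#' until fewer than `min_region` points remain. Regions smaller than
#' `min_region` are discarded to the residual.
#'
#' Determinism: global seeds are taken in `(curvature, index)` order, the
#' growth queue is FIFO and neighbor lists are distance-then-index ordered,
#' so identical input yields identical labels.
#'
#' @param cloud a [pod_cloud()] with normals and curvatures (see
#'   [estimate_normals_curvature()]).
#' @param graph the [build_neighbor_graph()] used for growth.
#' @param params a [growth_params()].
#' @return The cloud with `labels` filled (region ids dense from 0, residual
#'   `-1`) and a `regions` attribute: a data.frame of id, size and centroid.
#' @export
region_growing <- function(cloud, graph, params = growth_params()) {
  if (is.null(cloud$normals) || is.null(cloud$curvatures))
    stop("cloud must carry normals and curvatures; run estimate_normals_curvature()")
  stopifnot(inherits(graph, "pod_neighbor_graph"),
            inherits(params, "growth_params"))
  n <- cloud_size(cloud)
  if (graph$n != n) stop("neighbor graph was built on a different cloud")

  normals <- cloud$normals
  curv <- cloud$curvatures
  nbidx <- graph$neighbor_indices
  cos_thresh <- cos(params$angle_thresh * pi / 180)

  labels <- rep(-1L, n)
  avail <- rep(TRUE, n)
  seed_order <- order(curv, seq_len(n))
  ptr <- 1L
  region_id <- 0L
  remaining <- n

  while (remaining >= params$min_region) {
    while (ptr <= n && !avail[seed_order[ptr]]) ptr <- ptr + 1L
    if (ptr > n) break
    seed0 <- seed_order[ptr]
    queue <- integer(max(256L, params$min_region))
    queue[1L] <- seed0
    qlen <- 1L
    head <- 1L
    members <- integer(0)
    avail[seed0] <- FALSE
    members_buf <- integer(max(256L, params$min_region))
    members_buf[1L] <- seed0
    mlen <- 1L
    while (head <= qlen) {
      s <- queue[head]
      head <- head + 1L
      nb <- nbidx[s, ]
      nb <- nb[avail[nb]]
      if (length(nb) == 0) next
      dots <- abs(as.numeric(normals[nb, , drop = FALSE] %*% normals[s, ]))
      joined <- nb[dots > cos_thresh]
      if (length(joined) == 0) next
      avail[joined] <- FALSE
      if (mlen + length(joined) > length(members_buf))
        members_buf <- c(members_buf, integer(length(members_buf)))
      members_buf[mlen + seq_along(joined)] <- joined
      mlen <- mlen + length(joined)
      promote <- joined[curv[joined] < params$curv_thresh]
      if (length(promote)) {
        if (qlen + length(promote) > length(queue))
          queue <- c(queue, integer(length(queue)))
        queue[qlen + seq_along(promote)] <- promote
        qlen <- qlen + length(promote)
      }
    }
    members <- members_buf[seq_len(mlen)]
    remaining <- remaining - length(members)
    if (length(members) >= params$min_region) {
      labels[members] <- region_id
      region_id <- region_id + 1L
    }
  }

  out <- cloud
  out$labels <- labels
  attr(out, "regions") <- region_summary(out)
  out
}

#' Summarize labeled regions
#'
#' @param cloud a labeled [pod_cloud()].
#' @return data.frame with columns `id`, `size`, `cx`, `cy`, `cz` (residual
#'   excluded).
#' @export
region_summary <- function(cloud) {
  if (is.null(cloud$labels)) stop("cloud has no labels")
  ids <- sort(setdiff(unique(cloud$labels), -1L))
  if (length(ids) == 0)
    return(data.frame(id = integer(0), size = integer(0),
                      cx = numeric(0), cy = numeric(0), cz = numeric(0)))
  do.call(rbind, lapply(ids, function(id) {
    sel <- cloud$labels == id
    ctr <- colMeans(cloud$points[sel, , drop = FALSE])
    data.frame(id = id, size = sum(sel), cx = ctr[1], cy = ctr[2], cz = ctr[3],
               row.names = NULL)
  }))
}

#' Extract one labeled region as a cloud
#' @param cloud a labeled [pod_cloud()].
#' @param id region id.
#' @return A [pod_cloud()] of that region's points.
#' @export
region_cloud <- function(cloud, id) {
  if (is.null(cloud$labels)) stop("cloud has no labels")
  sel <- cloud$labels == id
  if (!any(sel)) stop("no points with label ", id)
  cloud_subset(cloud, sel)
}
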