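# Independent brute-force oracles used to validate the compiled/optimized
# implementations. Deliberately naive: linear scans, no spatial indexing.

# exact k nearest neighbors by full distance sort (ties by lower index)
naive_knn <- function(P, k) {
  n <- nrow(P)
  kk <- min(k, n - 1)
  idx <- matrix(0L, n, kk)
  for (i in seq_len(n)) {
    d <- sqrt(colSums((t(P) - P[i, ])^2))
    d[i] <- Inf
    idx[i, ] <- order(d, seq_len(n))[seq_len(kk)]
  }
  idx
}

# exhaustive O(M^3) rolling-ball edge set
naive_rollball <- function(P, r, eps = 1e-9 * r) {
  M <- nrow(P)
  E <- matrix(integer(0), 0, 2)
  for (i in seq_len(M - 1)) for (j in (i + 1):M) {
    v <- P[j, ] - P[i, ]
    L2 <- sum(v^2)
    if (L2 > 4 * r^2 || L2 == 0) next
    L <- sqrt(L2)
    D <- sqrt(max(0, r^2 - L2 / 4))
    C <- (P[i, ] + P[j, ]) / 2
    H <- c(-v[2], v[1]) / L
    edge <- FALSE
    for (s in c(-1, 1)) {
      O <- C + s * D * H
      d <- sqrt(colSums((t(P) - O)^2))
      d[c(i, j)] <- Inf
      if (all(d >= r - eps)) { edge <- TRUE; break }
    }
    if (edge) E <- rbind(E, c(i, j))
  }
  E
}

# straight re-implementation of the two-tier region growing with linear-scan
# neighbor search; intentionally shares no code with the package version
naive_region_growing <- function(points, normals, curv, k, angle_deg,
                                 curv_thresh, min_region) {
  n <- nrow(points)
  nb <- naive_knn(points, k)
  cosang <- cos(angle_deg * pi / 180)
  labels <- rep(-1L, n)
  free <- rep(TRUE, n)
  next_id <- 0L
  remaining <- n
  ord <- order(curv, seq_len(n))
  while (remaining >= min_region) {
    seed <- NA_integer_
    for (i in ord) if (free[i]) { seed <- i; break }
    if (is.na(seed)) break
    queue <- seed
    free[seed] <- FALSE
    members <- seed
    while (length(queue)) {
      s <- queue[1]
      queue <- queue[-1]
      for (j in nb[s, ]) {
        if (!free[j]) next
        if (abs(sum(normals[s, ] * normals[j, ])) > cosang) {
          free[j] <- FALSE
          members <- c(members, j)
          if (curv[j] < curv_thresh) queue <- c(queue, j)
        }
      }
    }
    remaining <- remaining - length(members)
    if (length(members) >= min_region) {
      labels[members] <- next_id
      next_id <- next_id + 1L
    }
  }
  labels
}

# purity of predicted labels against truth labels (residual ignored)
label_purity <- function(pred, truth) {
  assigned <- pred != -1L
  if (!any(assigned)) return(0)
  agree <- 0
  for (r in unique(pred[assigned])) {
    sel <- pred == r
    agree <- agree + max(table(truth[sel]))
  }
  agree / sum(assigned)
}

# filled ellipse test image (rows x cols, 1-based center)
ellipse_image <- function(nr, nc, cx, cy, a, b, theta = 0,
                          fg = 0.9, bg = 0.1) {
  x <- matrix(rep(seq_len(nc), each = nr), nr)
  y <- matrix(rep(seq_len(nr), nc), nr)
  dx <- x - cx; dy <- y - cy
  u <- cos(theta) * dx + sin(theta) * dy
  v <- -sin(theta) * dx + cos(theta) * dy
  ifelse((u / a)^2 + (v / b)^2 <= 1, fg, bg)
}

# directed Hausdorff distance between two 2D point sets
hausdorff2 <- function(A, B) {
  h <- function(X, Y) max(apply(X, 1, function(p)
    min(sqrt(colSums((t(Y) - p)^2)))))
  max(h(A, B), h(B, A))
}
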