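#' Per-object pixel accuracy
#'
#' `P = 100 * K1 / K2` where `K1` is the matched pixel count of one object
#' and `K2` its reference (complete) pixel count. Values above 100 are
#' reported as-is with an over-segmentation warning.
#'
#' @param K1 matched pixel count (>= 0).
#' @param K2 reference pixel count (> 0).
#' @return Accuracy percentage.
#' @export
pixel_accuracy <- function(K1, K2) {
  if (K2 <= 0) stop("undefined metric: reference pixel count K2 must be > 0")
  if (K1 < 0) stop("K1 must be >= 0")
  P <- 100 * K1 / K2
  if (P > 100) warning(sprintf("accuracy %.2f%% > 100%%: over-segmentation", P))
  P
}

#' Mean success rate over a group of objects
#'
#' Pixel-weighted success rate `sigma = 100 * sum(z) / sum(Z)` over `m`
#' objects with matched counts `z` and reference counts `Z` (not the mean of
#' per-object ratios). With `m = 1` this reduces to [pixel_accuracy()].
#'
#' @param z per-object matched pixel counts.
#' @param Z per-object reference pixel counts (sum must be positive).
#' @return Percentage in `[0, 100]` when `z <= Z` elementwise.
#' @export
mean_success_rate <- function(z, Z) {
  if (length(z) != length(Z)) stop("z and Z must have equal length")
  if (length(z) < 1) stop("need at least one object")
  if (sum(Z) <= 0) stop("sum of reference counts must be positive")
  100 * sum(z) / sum(Z)
}

#' Score predicted instance masks against ground truth
#'
#' Assigns predicted to truth masks one-to-one by maximizing total IoU
#' (exact enumeration up to 7 objects, greedy beyond), then computes the
#' per-object accuracy and the pixel-weighted mean success rate. In
#' `"intersection"` mode the matched count `K1` is `|predicted & truth|`, so
#' over-segmentation cannot inflate the score; `"raw"` mode counts all
#' predicted pixels of the assigned mask, which mirrors scoring against a
#' reference count when no truth masks exist.
#'
#' @param pred_masks list of logical matrices (predicted instances).
#' @param truth_masks list of logical matrices (reference instances, >= 1).
#' @param mode `"intersection"` (default) or `"raw"`.
#' @return An object of class `segmentation_score`: data.frame `per_object`
#'   (truth id, assigned prediction, K1, K2, P, IoU), `sigma`, `mode`.
#' @export
score_scene <- function(pred_masks, truth_masks,
                        mode = c("intersection", "raw")) {
  mode <- match.arg(mode)
  if (length(truth_masks) < 1) stop("need at least one truth mask")
  m <- length(truth_masks); n <- length(pred_masks)
  iou <- matrix(0, m, n)
  inter <- matrix(0, m, n)
  for (i in seq_len(m)) for (j in seq_len(n)) {
    ti <- truth_masks[[i]]; pj <- pred_masks[[j]]
    ii <- sum(ti & pj)
    inter[i, j] <- ii
    iou[i, j] <- if (ii > 0) ii / sum(ti | pj) else 0
  }
  assign <- assign_by_iou(iou)
  K2 <- vapply(truth_masks, sum, numeric(1))
  K1 <- numeric(m); iou_m <- numeric(m)
  for (i in seq_len(m)) {
    j <- assign[i]
    if (!is.na(j)) {
      K1[i] <- if (mode == "intersection") inter[i, j]
               else sum(pred_masks[[j]])
      iou_m[i] <- iou[i, j]
    }
  }
  per_object <- data.frame(truth = seq_len(m), pred = assign,
                           K1 = K1, K2 = K2,
                           P = 100 * K1 / K2, IoU = iou_m)
  structure(list(per_object = per_object,
                 sigma = mean_success_rate(K1, K2),
                 mode = mode),
            class = "segmentation_score")
}

#' @export
print.segmentation_score <- function(x, ...) {
  cat(sprintf("segmentation_score (%s mode): sigma = %.2f%%\n", x$mode, x$sigma))
  print(x$per_object, row.names = FALSE)
  invisible(x)
}

# maximize total IoU; returns per-truth assigned prediction index (NA = none)
assign_by_iou <- function(iou) {
  m <- nrow(iou); n <- ncol(iou)
  if (n == 0) return(rep(NA_integer_, m))
  if (min(m, n) <= 7) {
    small_on_rows <- m <= n
    k <- min(m, n)
    perms <- permutations_of(max(m, n), k)
    best <- NULL; best_val <- -Inf
    for (p in seq_len(nrow(perms))) {
      sel <- perms[p, ]
      val <- if (small_on_rows) sum(iou[cbind(seq_len(m), sel)])
             else sum(iou[cbind(sel, seq_len(n))])
      if (val > best_val) { best_val <- val; best <- sel }
    }
    assign <- rep(NA_integer_, m)
    if (small_on_rows) assign <- best
    else assign[best] <- seq_len(n)
  } else {
    assign <- rep(NA_integer_, m)
    taken <- logical(n)
    ord <- order(-iou)
    for (lin in ord) {
      i <- (lin - 1) %% m + 1; j <- (lin - 1) %/% m + 1
      if (iou[i, j] <= 0) break
      if (is.na(assign[i]) && !taken[j]) { assign[i] <- j; taken[j] <- TRUE }
    }
  }
  assign[!is.na(assign) & vapply(seq_len(m), function(i)
    !is.na(assign[i]) && iou[i, assign[i]] <= 0, logical(1))] <- NA_integer_
  assign
}

# all ordered selections of k items from n (n^k grows, so k <= 7 callers only)
permutations_of <- function(n, k) {
  if (k == 1) return(matrix(seq_len(n), ncol = 1))
  sub <- permutations_of(n, k - 1)
  out <- NULL
  for (v in seq_len(n)) {
    rows <- sub[rowSums(sub == v) == 0, , drop = FALSE]
    out <- rbind(out, cbind(v, rows))
  }
  unname(out)
}
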