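#' Difference-of-Gaussian focus filter
#'
#' Plane-wise focus filtering of a transmission stack:
#' \eqn{I' = |I - G_\sigma * I|} with a 2D Gaussian kernel applied to each
#' z-plane independently, which responds to in-focus edges. The default
#' sigma is 1 voxel.
#'
#' @param stack a [voxel_stack()] with finite intensities.
#' @param sigma Gaussian standard deviation in voxels (> 0).
#' @return a [voxel_stack()] of the same shape, non-negative.
#' @export
dog_filter <- function(stack, sigma = 1) {
  if (!is.finite(sigma) || sigma <= 0) stopf("sigma must be > 0")
  if (!all(is.finite(stack))) stopf("stack contains non-finite voxels")
  a <- unclass(stack)
  attributes(a) <- list(dim = dim(stack))
  blurred <- EBImage::gblur(a, sigma = sigma)
  rebuild_stack(abs(a - blurred), stack)
}

# 3x3 plane-wise median filter via a median-of-9 comparator network.
# Vectorised pmin/pmax on whole planes; borders replicate.
median3x3 <- function(stack) {
  a <- unclass(stack)
  dims <- dim(a)
  out <- a
  shift2 <- function(m, di, dj) {
    ni <- nrow(m); nj <- ncol(m)
    m[clamp(seq_len(ni) + di, 1L, ni), clamp(seq_len(nj) + dj, 1L, nj)]
  }
  med3 <- function(x, y, z) pmax(pmin(x, y), pmin(pmax(x, y), z))
  for (k in seq_len(dims[3L])) {
    p <- a[, , k]
    n <- vector("list", 9L)
    idx <- 1L
    for (di in -1:1) for (dj in -1:1) {
      n[[idx]] <- shift2(p, di, dj); idx <- idx + 1L
    }
    # sort each row-triple, then median of (max of mins, median of mids,
    # min of maxes)
    lo <- list(); mi <- list(); hi <- list()
    for (g in 0:2) {
      x <- n[[3 * g + 1L]]; y <- n[[3 * g + 2L]]; z <- n[[3 * g + 3L]]
      lo[[g + 1L]] <- pmin(x, y, z)
      hi[[g + 1L]] <- pmax(x, y, z)
      mi[[g + 1L]] <- med3(x, y, z)
    }
    out[, , k] <- med3(pmax(lo[[1L]], lo[[2L]], lo[[3L]]),
                       med3(mi[[1L]], mi[[2L]], mi[[3L]]),
                       pmin(hi[[1L]], hi[[2L]], hi[[3L]]))
  }
  if (inherits(stack, "voxel_stack")) rebuild_stack(out, stack) else out
}

#' Detect nuclei as prominent local intensity maxima
#'
#' Smooths each plane with a Gaussian (sigma 1 voxel by default), finds 3D
#' local maxima (26-neighbourhood) above `threshold`, then discards maxima
#' that are not separated from any higher retained maximum by a deep enough
#' saddle: a maximum is kept only if its height exceeds the level at which
#' its superlevel component merges with a higher maximum's component by at
#' least `min_prominence` gray levels. Defaults follow typical nuclear
#' light-sheet settings (threshold 150, prominence 30).
#'
#' @param stack a [voxel_stack()].
#' @param sigma smoothing sigma in voxels; 0 disables smoothing.
#' @param threshold minimum (smoothed) intensity of a detection.
#' @param min_prominence minimum saddle depth to a higher maximum, gray
#'   levels.
#' @return data.frame with columns `x_um`, `y_um`, `z_um`, `intensity`
#'   (smoothed), one row per detected nucleus; zero rows allowed.
#' @export
detect_nuclei <- function(stack, sigma = 1, threshold = 150,
                          min_prominence = 30) {
  sm <- if (sigma > 0) {
    a <- unclass(stack); attributes(a) <- list(dim = dim(stack))
    EBImage::gblur(a, sigma = sigma)
  } else {
    a <- unclass(stack); attributes(a) <- list(dim = dim(stack)); a
  }
  dims <- dim(sm)
  peaks <- local_maxima_3d(sm, threshold)
  if (!nrow(peaks)) {
    return(data.frame(x_um = numeric(), y_um = numeric(), z_um = numeric(),
                      intensity = numeric()))
  }
  keep <- prominence_filter(sm, peaks, threshold, min_prominence)
  peaks <- peaks[keep, , drop = FALSE]
  w <- voxel_to_world(peaks[, c("i", "j", "k")], stack)
  data.frame(x_um = w[, 1L], y_um = w[, 2L], z_um = w[, 3L],
             intensity = peaks$value)
}

# strict 26-neighbourhood local maxima above a threshold
local_maxima_3d <- function(a, threshold) {
  dims <- dim(a)
  cand <- which(a > threshold)
  if (!length(cand)) {
    return(data.frame(i = integer(), j = integer(), k = integer(),
                      value = numeric()))
  }
  ijk <- arrayInd(cand, dims)
  ok <- rep(TRUE, length(cand))
  for (di in -1:1) for (dj in -1:1) for (dk in -1:1) {
    if (di == 0 && dj == 0 && dk == 0) next
    ni <- clamp(ijk[, 1L] + di, 1L, dims[1L])
    nj <- clamp(ijk[, 2L] + dj, 1L, dims[2L])
    nk <- clamp(ijk[, 3L] + dk, 1L, dims[3L])
    nb <- a[cbind(ni, nj, nk)]
    same <- ni == ijk[, 1L] & nj == ijk[, 2L] & nk == ijk[, 3L]
    ok <- ok & (same | a[cand] > nb)
  }
  data.frame(i = ijk[ok, 1L], j = ijk[ok, 2L], k = ijk[ok, 3L],
             value = a[cand[ok]])
}

# Saddle-prominence filter by descending-level union-find flooding.
# Only levels down to threshold - min_prominence can affect the decision,
# so flooding is restricted to that superlevel set.
prominence_filter <- function(a, peaks, threshold, min_prominence) {
  dims <- dim(a)
  floor_level <- threshold - min_prominence
  flood <- which(a >= floor_level)
  ord <- flood[order(a[flood], decreasing = TRUE)]
  pos <- integer(prod(dims))          # rank of voxel in flood order, 0 = dry
  pos[ord] <- seq_along(ord)
  parent <- seq_along(ord)
  comp_peak <- numeric(length(ord))   # max height in each component
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  peak_lin <- peaks$i + (peaks$j - 1L) * dims[1L] +
    (peaks$k - 1L) * dims[1L] * dims[2L]
  saddle <- rep(-Inf, nrow(peaks))
  peak_rank <- pos[peak_lin]
  rank_to_peak <- integer(length(ord))
  rank_to_peak[peak_rank] <- seq_len(nrow(peaks))
  # track, per component root, the best peak index (highest value)
  comp_best <- integer(length(ord))
  off <- expand.grid(di = -1:1, dj = -1:1, dk = -1:1)
  off <- off[!(off$di == 0 & off$dj == 0 & off$dk == 0), ]
  ijk_all <- arrayInd(ord, dims)
  for (r in seq_along(ord)) {
    v <- ord[r]
    ijk <- ijk_all[r, ]
    comp_peak[r] <- a[v]
    comp_best[r] <- rank_to_peak[r]   # 0 if this voxel is not a peak
    level <- a[v]
    for (q in seq_len(nrow(off))) {
      ni <- ijk[1L] + off$di[q]; nj <- ijk[2L] + off$dj[q]
      nk <- ijk[3L] + off$dk[q]
      if (ni < 1L || nj < 1L || nk < 1L ||
          ni > dims[1L] || nj > dims[2L] || nk > dims[3L]) next
      nlin <- ni + (nj - 1L) * dims[1L] + (nk - 1L) * dims[1L] * dims[2L]
      nr <- pos[nlin]
      if (nr == 0L || nr > r) next    # not flooded yet
      ra <- find(r); rb <- find(nr)
      if (ra == rb) next
      # merging two components at this level: the component with the lower
      # summit records its saddle
      if (comp_peak[ra] < comp_peak[rb]) { tmp <- ra; ra <- rb; rb <- tmp }
      pb <- comp_best[rb]
      if (pb > 0L && saddle[pb] < level) saddle[pb] <- level
      parent[rb] <- ra
      if (comp_best[ra] == 0L) comp_best[ra] <- comp_best[rb]
    }
  }
  heights <- peaks$value
  # prominence relative to the merge saddle; peaks that never merged keep
  # -Inf saddle and are always retained
  heights - saddle >= min_prominence
}
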