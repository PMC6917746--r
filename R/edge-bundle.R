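#' Parameters for force-directed edge bundling
#'
#' Standard force-directed bundling schedule: a fixed number of cycles, a
#' decreasing iteration count and step size per cycle, and a doubling
#' subdivision count, with pairwise compatibility gating which polylines
#' attract each other. The rendering transparency the bundled plots use is
#' carried along (default 0.95).
#'
#' @param n_cycles number of bundling cycles.
#' @param iterations iterations in the first cycle (reduced by 1/3 each
#'   subsequent cycle).
#' @param step initial displacement step (in data units; halved per cycle).
#' @param compatibility minimum pairwise compatibility in [0, 1] for two
#'   polylines to interact.
#' @param initial_subdivisions interior vertices in the first cycle
#'   (doubled each cycle).
#' @param spring_constant global spring stiffness K.
#' @param n_clusters polylines are pre-clustered into this many spatial
#'   groups (k-means on resampled coordinates) and bundled within groups
#'   only; 1 disables pre-clustering.
#' @param transparency alpha used when rendering bundles.
#' @return object of class `bundle_params`.
#' @export
bundle_params <- function(n_cycles = 6L, iterations = 50L, step = 0.04,
                          compatibility = 0.6, initial_subdivisions = 1L,
                          spring_constant = 0.1, n_clusters = 1L,
                          transparency = 0.95) {
  if (compatibility < 0 || compatibility > 1) {
    stopf("compatibility threshold must be in [0, 1]")
  }
  structure(list(n_cycles = n_cycles, iterations = iterations, step = step,
                 compatibility = compatibility,
                 initial_subdivisions = initial_subdivisions,
                 spring_constant = spring_constant,
                 n_clusters = n_clusters, transparency = transparency),
            class = "bundle_params")
}

# resample a polyline to n vertices by arc length
resample_polyline <- function(p, n) {
  p <- as.matrix(p)
  if (nrow(p) == 1L) return(p[rep(1L, n), , drop = FALSE])
  seg <- sqrt(rowSums(diff(p)^2))
  s <- c(0, cumsum(seg))
  if (s[length(s)] == 0) return(p[rep(1L, n), , drop = FALSE])
  target <- seq(0, s[length(s)], length.out = n)
  apply(p, 2L, function(col) stats::approx(s, col, xout = target)$y)
}

# Holten-style compatibility of two chords (angle, scale, position,
# visibility), each factor in [0, 1]
edge_compatibility <- function(p, q) {
  vp <- p[2L, ] - p[1L, ]; vq <- q[2L, ] - q[1L, ]
  lp <- sqrt(sum(vp^2)); lq <- sqrt(sum(vq^2))
  if (lp == 0 || lq == 0) return(0)
  c_angle <- abs(sum(vp * vq) / (lp * lq))
  lavg <- (lp + lq) / 2
  c_scale <- 2 / (lavg / min(lp, lq) + max(lp, lq) / lavg)
  mp <- (p[1L, ] + p[2L, ]) / 2; mq <- (q[1L, ] + q[2L, ]) / 2
  c_pos <- lavg / (lavg + sqrt(sum((mp - mq)^2)))
  vis <- function(a, b) {
    ab <- a[2L, ] - a[1L, ]
    t0 <- sum((b[1L, ] - a[1L, ]) * ab) / sum(ab^2)
    t1 <- sum((b[2L, ] - a[1L, ]) * ab) / sum(ab^2)
    i0 <- a[1L, ] + t0 * ab; i1 <- a[1L, ] + t1 * ab
    im <- (i0 + i1) / 2
    am <- (a[1L, ] + a[2L, ]) / 2
    max(0, 1 - 2 * sqrt(sum((am - im)^2)) / sqrt(sum((i1 - i0)^2) + 1e-300))
  }
  c_vis <- min(vis(p, q), vis(q, p))
  c_angle * c_scale * c_pos * c_vis
}

#' Force-directed bundling of trajectory polylines
#'
#' Pulls spatially compatible polylines toward each other to declutter
#' dense trajectory plots: endpoints stay fixed, interior vertices move
#' under spring forces along each polyline plus attraction between
#' corresponding vertices of compatible polyline pairs (compatibility from
#' angle, scale, position and visibility of the endpoint chords).
#' Polylines are optionally pre-clustered into spatial groups and bundled
#' within groups only. Deterministic given input order and parameters.
#'
#' @param polylines list of n x 2 (or n x 3) matrices/data.frames.
#' @param params a [bundle_params()].
#' @return list of bundled polylines (matrices), same length and endpoint
#'   positions as the input; attribute `compatibility` holds the pairwise
#'   matrix, `cluster` the pre-cluster labels.
#' @export
edge_bundle <- function(polylines, params = bundle_params()) {
  if (!length(polylines)) stopf("need at least one polyline")
  polys <- lapply(polylines, function(p) {
    p <- as.matrix(p)
    storage.mode(p) <- "double"
    p
  })
  n <- length(polys)
  if (n == 1L) return(polys)
  chords <- lapply(polys, function(p) p[c(1L, nrow(p)), , drop = FALSE])
  comp <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    comp[i, j] <- comp[j, i] <- edge_compatibility(chords[[i]], chords[[j]])
  }
  cluster <- rep(1L, n)
  if (params$n_clusters > 1L && n > params$n_clusters) {
    feat <- t(vapply(polys, function(p) as.numeric(resample_polyline(p, 8L)),
                     numeric(8L * ncol(polys[[1L]]))))
    ord <- order(feat[, 1L])
    ctr <- feat[ord[round(seq(1L, n, length.out = params$n_clusters))], ,
                drop = FALSE]
    cluster <- stats::kmeans(feat, centers = ctr, iter.max = 50L,
                             algorithm = "Lloyd")$cluster
  }
  P <- params$initial_subdivisions
  step <- params$step
  iters <- params$iterations
  for (cyc in seq_len(params$n_cycles)) {
    nv <- P + 2L
    polys <- lapply(polys, resample_polyline, n = nv)
    kp <- params$spring_constant / (P + 1L)
    for (it in seq_len(iters)) {
      forces <- lapply(polys, function(p) matrix(0, nrow(p), ncol(p)))
      for (i in seq_len(n)) {
        p <- polys[[i]]
        # spring forces toward neighbours along the polyline
        f <- matrix(0, nv, ncol(p))
        f[2:(nv - 1L), ] <- kp * ((p[1:(nv - 2L), , drop = FALSE] -
                                     p[2:(nv - 1L), , drop = FALSE]) +
                                    (p[3:nv, , drop = FALSE] -
                                       p[2:(nv - 1L), , drop = FALSE]))
        forces[[i]] <- forces[[i]] + f
      }
      for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
        if (cluster[i] != cluster[j]) next
        if (comp[i, j] < params$compatibility) next
        d <- polys[[j]] - polys[[i]]
        dist <- sqrt(rowSums(d^2))
        ok <- dist > 1e-12
        pull <- d * 0
        pull[ok, ] <- d[ok, , drop = FALSE] /
          (dist[ok] * (1 + dist[ok]))
        pull <- pull * comp[i, j]
        pull[c(1L, nv), ] <- 0
        forces[[i]] <- forces[[i]] + pull
        forces[[j]] <- forces[[j]] - pull
      }
      for (i in seq_len(n)) {
        f <- forces[[i]]
        f[c(1L, nv), ] <- 0
        polys[[i]] <- polys[[i]] + step * f
      }
    }
    P <- P * 2L
    step <- step / 2
    iters <- max(1L, round(iters * 2 / 3))
  }
  attr(polys, "compatibility") <- comp
  attr(polys, "cluster") <- cluster
  polys
}
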