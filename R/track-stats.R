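#' Straightness index of a trajectory
#'
#' SI = end-to-end distance divided by the summed step lengths (the actual
#' path length), a scale- and rotation-invariant measure of how directed a
#' cell's movement is: 1 for straight monotone motion, 0 for a closed loop.
#' A stationary track (zero path length) has no defined SI and returns
#' `NA` with a warning-free flag; aggregate helpers exclude such tracks.
#'
#' @param positions n x 3 matrix of Cartesian positions (n >= 2), um.
#' @return scalar in [0, 1], or `NA_real_` for zero path length.
#' @examples
#' straightness_index(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)))  # 1
#' straightness_index(rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0)))  # sqrt(2)/2
#' @export
straightness_index <- function(positions) {
  p <- as_position_matrix(positions)
  if (nrow(p) < 2L) stopf("a track needs at least 2 positions")
  steps <- diff(p)
  path <- sum(row_norms(steps))
  if (path <= 0) return(NA_real_)
  vec_norm(p[nrow(p), ] - p[1L, ]) / path
}

#' Per-track straightness of a track set
#'
#' @param ts a [track_set()].
#' @return data.frame with `cell_id`, `layer`, `n_frames`, `si`
#'   (`NA` where the path length is zero); attribute `n_undefined` counts
#'   excluded stationary tracks.
#' @export
track_straightness <- function(ts) {
  per <- lapply(track_split(ts), function(df) {
    si <- if (nrow(df) >= 2L) straightness_index(track_positions(df)) else NA_real_
    data.frame(cell_id = df$cell_id[1L], layer = df$layer[1L],
               n_frames = nrow(df), si = si)
  })
  out <- do.call(rbind, per)
  rownames(out) <- NULL
  attr(out, "n_undefined") <- sum(is.na(out$si))
  out
}

#' Straightness versus position with 90% prediction ellipses
#'
#' Subdivides every track into non-overlapping windows of `window_frames`
#' frames (default 10, about 20 min) aligned to the track start, computes
#' the SI of each window together with the spherical coordinates of the
#' window's midpoint position, and fits per-layer bivariate-normal
#' prediction ellipses to each (coordinate, SI) pair.
#'
#' @param ts a [track_set()].
#' @param frame a [spherical_frame()].
#' @param window_frames frames per window (>= 2).
#' @param level prediction level of the ellipses.
#' @return list with `points` (data.frame: `cell_id`, `layer`, `window`,
#'   `si`, `r`, `theta`, `phi`) and `ellipses` (per layer, per coordinate:
#'   [prediction_ellipse()] fits; `NULL` and flagged in `skipped` when a
#'   layer has fewer than 3 windows).
#' @export
si_position_analysis <- function(ts, frame = spherical_frame(),
                                 window_frames = 10L, level = 0.90) {
  if (window_frames < 2L) stopf("window_frames must be >= 2")
  rows <- lapply(track_split(ts), function(df) {
    n <- nrow(df)
    n_win <- n %/% window_frames
    if (n_win == 0L) return(NULL)
    do.call(rbind, lapply(seq_len(n_win), function(w) {
      seg <- df[((w - 1L) * window_frames + 1L):(w * window_frames), ]
      p <- track_positions(seg)
      mid <- to_spherical(rbind(p[ceiling(nrow(p) / 2), ]), frame)
      data.frame(cell_id = df$cell_id[1L], layer = df$layer[1L], window = w,
                 si = straightness_index(p),
                 r = mid$r, theta = mid$theta, phi = mid$phi)
    }))
  })
  pts <- do.call(rbind, rows)
  rownames(pts) <- NULL
  ellipses <- list()
  skipped <- character(0)
  for (lay in unique(pts$layer)) {
    sub <- pts[pts$layer == lay & !is.na(pts$si), ]
    if (nrow(sub) < 3L) {
      skipped <- c(skipped, lay)
      next
    }
    ellipses[[lay]] <- lapply(c(r = "r", theta = "theta", phi = "phi"),
                              function(co) {
                                prediction_ellipse(cbind(sub[[co]], sub$si),
                                                   level = level)
                              })
  }
  list(points = pts, ellipses = ellipses, skipped = skipped)
}

#' Bivariate-normal prediction ellipse
#'
#' The ellipse enclosing the region where a stated fraction of new
#' observations would fall if the data were bivariate normal: centred on
#' the sample mean, shaped by the sample covariance, with squared
#' Mahalanobis radius equal to the chi-square(2) quantile of `level`
#' (semi-axes scale by `sqrt(qchisq(level, 2))`, about 2.146 at 90%).
#'
#' @param xy n x 2 matrix of observations (n >= 3).
#' @param level coverage level in (0, 1).
#' @return list of class `prediction_ellipse`: `center`, `cov`, `level`,
#'   `radius` (`sqrt(qchisq(level, 2))`), `semi_axes` (descending), `angle`
#'   of the major axis, and `n`.
#' @export
prediction_ellipse <- function(xy, level = 0.90) {
  xy <- as.matrix(xy)
  if (ncol(xy) != 2L || nrow(xy) < 3L) {
    stopf("prediction_ellipse needs an n x 2 matrix with n >= 3")
  }
  ctr <- colMeans(xy)
  S <- stats::cov(xy)
  e <- eigen(S, symmetric = TRUE)
  radius <- sqrt(stats::qchisq(level, df = 2L))
  structure(list(center = ctr, cov = S, level = level, radius = radius,
                 semi_axes = radius * sqrt(pmax(e$values, 0)),
                 angle = atan2(e$vectors[2L, 1L], e$vectors[1L, 1L]),
                 n = nrow(xy)),
            class = "prediction_ellipse")
}

#' Test whether points fall inside a prediction ellipse
#' @param ellipse a [prediction_ellipse()].
#' @param xy n x 2 matrix.
#' @return logical vector.
#' @export
in_ellipse <- function(ellipse, xy) {
  xy <- as.matrix(xy)
  d <- sweep(xy, 2L, ellipse$center)
  md2 <- rowSums((d %*% solve(ellipse$cov)) * d)
  md2 <= ellipse$radius^2
}

#' Relative cell counts per germ layer
#'
#' Per-frame fraction of detected cells in each layer, normalised by the
#' total across the three layers; fractions sum to exactly 1 at every
#' frame with at least one cell, and are `NA` (flagged) at empty frames.
#'
#' @param ts a [track_set()] with layer labels.
#' @param frames optional frame range to tabulate (default: all observed).
#' @return data.frame with columns `frame`, `epiblast`, `mesendoderm`,
#'   `endoderm`, `n_total`.
#' @export
relative_cell_counts <- function(ts, frames = NULL) {
  d <- ts$data
  if (is.null(frames)) frames <- seq(min(d$frame), max(d$frame))
  layers <- c("epiblast", "mesendoderm", "endoderm")
  tab <- table(factor(d$frame, levels = frames),
               factor(d$layer, levels = layers))
  tot <- rowSums(tab)
  frac <- sweep(unclass(tab), 1L, ifelse(tot > 0, tot, NA), `/`)
  out <- data.frame(frame = as.integer(rownames(tab)), frac,
                    n_total = as.integer(tot))
  names(out)[2:4] <- layers
  rownames(out) <- NULL
  out
}

#' Mean radial position per layer, normalised to a reference layer
#'
#' Per-frame mean radial coordinate of each germ layer divided by the
#' reference layer's mean radius at the same frame (mesendoderm by
#' default), exposing radial stratification of the layers over time.
#' Frames where the reference layer is empty are flagged `NA`.
#'
#' @param ts a [track_set()].
#' @param frame a [spherical_frame()].
#' @param reference reference layer name.
#' @return data.frame with `frame`, `layer`, `mean_r`, `rel_r`.
#' @export
mean_radial_position <- function(ts, frame = spherical_frame(),
                                 reference = "mesendoderm") {
  d <- ts$data
  sp <- to_spherical(track_positions(d), frame)
  agg <- stats::aggregate(sp$r, list(frame = d$frame, layer = d$layer), mean)
  names(agg)[3L] <- "mean_r"
  ref <- agg[agg$layer == reference, c("frame", "mean_r")]
  names(ref)[2L] <- "ref_r"
  out <- merge(agg, ref, by = "frame", all.x = TRUE)
  out$rel_r <- out$mean_r / out$ref_r
  out$ref_r <- NULL
  out[order(out$frame, out$layer), ]
}

#' Average per-track change in radius and latitude
#'
#' Cuts each track into non-overlapping pieces of fixed duration (10 min
#' by default), takes the last-minus-first difference of the spherical
#' radius and latitude per piece, and averages the piece differences per
#' track. Tracks shorter than one full piece are excluded and counted.
#'
#' @param ts a [track_set()].
#' @param frame a [spherical_frame()].
#' @param piece_minutes piece duration, minutes.
#' @param time_range optional `c(from, to)` hpf window applied first.
#' @return data.frame with `cell_id`, `layer`, `mean_dr` (um),
#'   `mean_dphi` (rad), `n_pieces`; attribute `n_excluded`.
#' @export
radius_latitude_change <- function(ts, frame = spherical_frame(),
                                   piece_minutes = 10, time_range = NULL) {
  piece_frames <- max(2L, round(piece_minutes * 60 / ts$frame_interval) + 1L)
  excluded <- 0L
  rows <- lapply(track_split(ts), function(df) {
    if (!is.null(time_range)) {
      df <- df[df$time_hpf >= time_range[1L] & df$time_hpf <= time_range[2L], ]
    }
    n <- nrow(df)
    n_pieces <- n %/% piece_frames
    if (n_pieces == 0L) {
      excluded <<- excluded + 1L
      return(NULL)
    }
    sp <- to_spherical(track_positions(df), frame)
    dr <- numeric(n_pieces); dphi <- numeric(n_pieces)
    for (p in seq_len(n_pieces)) {
      i0 <- (p - 1L) * piece_frames + 1L
      i1 <- p * piece_frames
      dr[p] <- sp$r[i1] - sp$r[i0]
      dphi[p] <- sp$phi[i1] - sp$phi[i0]
    }
    data.frame(cell_id = df$cell_id[1L], layer = df$layer[1L],
               mean_dr = mean(dr), mean_dphi = mean(dphi),
               n_pieces = n_pieces)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(cell_id = numeric(0), layer = character(0),
                      mean_dr = numeric(0), mean_dphi = numeric(0),
                      n_pieces = integer(0))
  }
  rownames(out) <- NULL
  attr(out, "n_excluded") <- excluded
  out
}

#' Filter tracks by longitude region and time window
#'
#' Retains tracks near a longitude band (the shield region
#' \eqn{[-\pi/8, \pi/8]} by default) within a time window. With
#' `completeness = "full"` a track must additionally span the whole window
#' (incomplete tracks are excluded, as for long-term track selections).
#'
#' @param ts a [track_set()].
#' @param frame a [spherical_frame()].
#' @param theta_range length-2 longitude range, rad.
#' @param time_range optional `c(from, to)` hpf window.
#' @param completeness `"full"` (track must span the window) or `"any"`.
#' @param predicate `"all"` (every in-window position must satisfy the
#'   longitude range) or `"any"` (at least one).
#' @return filtered [track_set()] (possibly empty; the number of dropped
#'   tracks is reported in the `n_dropped` attribute of the result's data).
#' @export
filter_tracks_region <- function(ts, frame = spherical_frame(),
                                 theta_range = c(-pi / 8, pi / 8),
                                 time_range = NULL,
                                 completeness = c("full", "any"),
                                 predicate = c("all", "any")) {
  completeness <- match.arg(completeness)
  predicate <- match.arg(predicate)
  keep_rows <- lapply(track_split(ts), function(df) {
    sub <- df
    if (!is.null(time_range)) {
      sel <- df$time_hpf >= time_range[1L] & df$time_hpf <= time_range[2L]
      sub <- df[sel, , drop = FALSE]
      if (!nrow(sub)) return(NULL)
      if (completeness == "full") {
        span_frames <- length(unique(ts$data$frame[
          ts$data$time_hpf >= time_range[1L] &
            ts$data$time_hpf <= time_range[2L]]))
        if (nrow(sub) < span_frames) return(NULL)
      }
    }
    th <- to_spherical(track_positions(sub), frame)$theta
    inside <- th >= theta_range[1L] & th <= theta_range[2L]
    ok <- if (predicate == "all") all(inside) else any(inside)
    if (ok) sub else NULL
  })
  kept <- do.call(rbind, keep_rows)
  n_dropped <- n_tracks(ts) - length(unique(kept$cell_id))
  if (is.null(kept)) {
    kept <- ts$data[0, ]
    n_dropped <- n_tracks(ts)
  }
  out <- track_set(kept, frame_interval = ts$frame_interval,
                   embryo_id = ts$embryo_id)
  attr(out, "n_dropped") <- n_dropped
  out
}
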