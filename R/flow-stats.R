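#' Circular correlation of two direction fields
#'
#' Correlates the flow directions of two germ layers at shared grid sites:
#' \deqn{\rho = E[\sin\alpha \sin\beta] / \sqrt{E[\sin^2\alpha]\,
#' E[\sin^2\beta]}}
#' with both central directions fixed at 0 (they are not identifiable for
#' near-uniform direction distributions). Under this convention
#' \eqn{\rho(\alpha,\alpha) = 1} and \eqn{\rho(\alpha,\alpha+\pi) = -1}
#' exactly. Applied per time interval over the sites where both fields
#' have observations, weighted by the smaller of the two observation
#' counts.
#'
#' @param field_a,field_b [build_flow_field()] results on the same layout.
#' @param weighted weight site pairs by `min(w_a, w_b)`.
#' @return data.frame with `interval`, `rho`, `n_sites` (`rho` is `NA`,
#'   flagged via `zero_variance`, when either field has no sine variance).
#' @export
circular_correlation <- function(field_a, field_b, weighted = TRUE) {
  if (!isTRUE(all.equal(field_a$grid, field_b$grid)) ||
      !isTRUE(all.equal(field_a$interval_breaks, field_b$interval_breaks))) {
    stopf("flow field layouts differ")
  }
  n_t <- dim(field_a$weight)[3L]
  out <- data.frame(interval = seq_len(n_t), rho = NA_real_,
                    n_sites = 0L, zero_variance = FALSE)
  for (t in seq_len(n_t)) {
    sel <- field_a$weight[, , t] > 0 & field_b$weight[, , t] > 0 &
      !is.na(field_a$ux[, , t]) & !is.na(field_b$ux[, , t])
    if (!any(sel)) next
    alpha <- atan2(field_a$uy[, , t][sel], field_a$ux[, , t][sel])
    beta <- atan2(field_b$uy[, , t][sel], field_b$ux[, , t][sel])
    w <- if (weighted) {
      pmin(field_a$weight[, , t][sel], field_b$weight[, , t][sel])
    } else rep(1, sum(sel))
    out$n_sites[t] <- sum(sel)
    r <- circ_corr(alpha, beta, w)
    out$rho[t] <- r
    out$zero_variance[t] <- is.na(r)
  }
  out
}

#' Circular correlation of paired angles (central directions fixed at 0)
#' @param alpha,beta paired angles, radians.
#' @param w optional non-negative weights.
#' @return scalar correlation in [-1, 1], `NA` if either sine second
#'   moment is zero.
#' @export
circ_corr <- function(alpha, beta, w = NULL) {
  if (is.null(w)) w <- rep(1, length(alpha))
  sa <- sin(alpha); sb <- sin(beta)
  va <- sum(w * sa^2); vb <- sum(w * sb^2)
  if (va <= 0 || vb <= 0) return(NA_real_)
  sum(w * sa * sb) / sqrt(va * vb)
}

#' Decompose a flow field into epiboly and convergence proportions
#'
#' Projects the unit flow direction at every populated grid site onto the
#' local reference directions for pure epiboly (toward the vegetal pole
#' along meridians) and pure convergence (toward the dorsal midline along
#' parallels), both expressed in the Mercator tangent plane where the
#' conformal projection keeps them orthonormal: epiboly is (0, 1) and
#' convergence is (-sign(u), 0). The projection s = v . ref (the cosine
#' of the angle) maps to a proportion
#' \deqn{p = 1 - (2/\pi)\arccos(s)} for s > 0 and p = 0 otherwise, so a
#' perfectly aligned site scores 1, an orthogonal or opposed site 0, and a
#' 45-degree site 0.5. The per-interval summary o(t) is the mean of p over
#' sites weighted by the observation counts; sites with a degenerate
#' convergence reference (on the dorsal/ventral meridians) are excluded
#' from the convergence sums.
#'
#' @param field a [build_flow_field()] / [average_flow_fields()] result.
#' @return object of class `flow_decomposition`: arrays `s_epi`, `s_conv`,
#'   `p_epi`, `p_conv` (grid x intervals) and a data.frame `summary` with
#'   `interval`, `t_mid_hpf`, `o_epi`, `o_conv`, `n_obs`.
#' @export
decompose_movement <- function(field) {
  g <- field$grid
  n_t <- dim(field$weight)[3L]
  dims <- dim(field$weight)
  s_epi <- array(NA_real_, dims); s_conv <- array(NA_real_, dims)
  p_epi <- array(NA_real_, dims); p_conv <- array(NA_real_, dims)
  conv_sign <- -sign(g$u_centers)          # toward u = 0
  conv_ok <- abs(g$u_centers) > 1e-12
  summary <- data.frame(interval = seq_len(n_t),
                        t_mid_hpf = (field$interval_breaks[-1L] +
                                       field$interval_breaks[-(n_t + 1L)]) / 2,
                        o_epi = NA_real_, o_conv = NA_real_, n_obs = 0L)
  for (t in seq_len(n_t)) {
    w <- field$weight[, , t]
    has <- w > 0 & !is.na(field$ux[, , t])
    if (!any(has)) next
    se <- field$uy[, , t]                   # v . (0, 1)
    sc <- field$ux[, , t] * matrix(conv_sign, g$n_u, g$n_v)
    pe <- proportion_from_projection(se)
    pc <- proportion_from_projection(sc)
    s_epi[, , t][has] <- se[has]; p_epi[, , t][has] <- pe[has]
    okc <- has & matrix(conv_ok, g$n_u, g$n_v)
    s_conv[, , t][okc] <- sc[okc]; p_conv[, , t][okc] <- pc[okc]
    summary$o_epi[t] <- sum(pe[has] * w[has]) / sum(w[has])
    if (any(okc)) {
      summary$o_conv[t] <- sum(pc[okc] * w[okc]) / sum(w[okc])
    }
    summary$n_obs[t] <- sum(w[has])
  }
  structure(list(s_epi = s_epi, s_conv = s_conv, p_epi = p_epi,
                 p_conv = p_conv, summary = summary, grid = g),
            class = "flow_decomposition")
}

#' Map a direction projection to a movement proportion
#'
#' `p = 1 - (2/pi) * acos(s)` for `s > 0`, else 0: 1 when the flow is
#' exactly along the reference, 0.5 at 45 degrees, 0 at orthogonal or
#' opposed.
#' @param s projection (cosine of the angle to the reference), in [-1, 1].
#' @return proportion in [0, 1].
#' @export
proportion_from_projection <- function(s) {
  p <- 1 - (2 / pi) * acos(clamp(s, -1, 1))
  ifelse(is.na(s) | s <= 0, ifelse(is.na(s), NA_real_, 0), p)
}

#' @export
print.flow_decomposition <- function(x, ...) {
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' @export
plot.flow_decomposition <- function(x, ...) {
  s <- x$summary
  graphics::plot(s$t_mid_hpf, s$o_epi, type = "b", ylim = c(0, 1),
                 xlab = "time (hpf)", ylab = "movement proportion o(t)",
                 col = "#1b9e77", pch = 16, ...)
  graphics::lines(s$t_mid_hpf, s$o_conv, type = "b", col = "#d95f02",
                  pch = 17)
  graphics::legend("topright", legend = c("epiboly", "convergence"),
                   col = c("#1b9e77", "#d95f02"), pch = c(16, 17), bty = "n")
  invisible(x)
}

# motion vectors over a window in spherical components, for every cell
# present at both window endpoints; returns start positions too
window_motion <- function(ts, frame, f0, f1) {
  d <- ts$data
  a <- d[d$frame == f0, ]
  b <- d[d$frame == f1, ]
  common <- intersect(a$cell_id, b$cell_id)
  if (!length(common)) return(NULL)
  a <- a[match(common, a$cell_id), ]
  b <- b[match(common, b$cell_id), ]
  pa <- track_positions(a); pb <- track_positions(b)
  sa <- to_spherical(pa, frame); sb <- to_spherical(pb, frame)
  list(cell_id = common, pos = pa,
       d_r = sb$r - sa$r,
       d_theta = wrap_angle(sb$theta - sa$theta),
       d_phi = sb$phi - sa$phi,
       r = sa$r, theta = sa$theta, phi = sa$phi)
}

# k nearest neighbour indices of each row of A among rows of B
# (3D Euclidean); self matches excluded via exclude_self when A and B are
# the same point set
knn_index <- function(A, B, k, exclude_self = FALSE) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * A %*% t(B)
  if (exclude_self) diag(d2) <- Inf
  idx <- apply(d2, 1L, function(r) order(r)[seq_len(k)])
  if (k == 1L) matrix(idx, ncol = 1L) else t(idx)
}

#' Correlation of local single-cell motion directions
#'
#' For each cell at sampled time points: the end-to-end motion vector of
#' its local track segment (default 10 min) and the average motion vector
#' of its `k` (default 6) nearest neighbour cells in the reference set,
#' both split into spherical components (r, theta, phi); per time point
#' the Spearman rank correlation between cell and neighbour motion is
#' computed for each component over all cells.
#'
#' @param ts_a track set providing the focal cells.
#' @param ts_b track set providing the neighbours (may equal `ts_a`, in
#'   which case a cell is excluded from its own neighbourhood).
#' @param frame a [spherical_frame()].
#' @param k number of nearest neighbours.
#' @param window_min motion-segment duration, minutes.
#' @param stride_frames spacing of evaluated time points (default: the
#'   window length).
#' @return data.frame with `frame`, `time_hpf`, `rho_r`, `rho_theta`,
#'   `rho_phi`, `n_cells`; components with zero variance give `NA`.
#' @export
local_motion_correlation <- function(ts_a, ts_b = ts_a,
                                     frame = spherical_frame(), k = 6L,
                                     window_min = 10, stride_frames = NULL) {
  wf <- max(1L, round(window_min * 60 / ts_a$frame_interval))
  if (is.null(stride_frames)) stride_frames <- wf
  same_set <- identical(ts_a$data, ts_b$data)
  frames <- sort(unique(ts_a$data$frame))
  f_eval <- frames[seq(1L, length(frames) - wf, by = stride_frames)]
  rows <- lapply(f_eval, function(f0) {
    ma <- window_motion(ts_a, frame, f0, f0 + wf)
    mb <- window_motion(ts_b, frame, f0, f0 + wf)
    if (is.null(ma) || is.null(mb)) return(NULL)
    need <- k + as.integer(same_set)
    if (length(mb$cell_id) < need) return(NULL)
    nn <- knn_index(ma$pos, mb$pos, k, exclude_self = same_set)
    nb_r <- rowMeans(matrix(mb$d_r[nn], nrow(nn)))
    nb_th <- rowMeans(matrix(mb$d_theta[nn], nrow(nn)))
    nb_ph <- rowMeans(matrix(mb$d_phi[nn], nrow(nn)))
    sp_cor <- function(x, y) {
      if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
      stats::cor(x, y, method = "spearman")
    }
    t0 <- ts_a$data$time_hpf[match(f0, ts_a$data$frame)]
    data.frame(frame = f0, time_hpf = t0,
               rho_r = sp_cor(ma$d_r, nb_r),
               rho_theta = sp_cor(ma$d_theta, nb_th),
               rho_phi = sp_cor(ma$d_phi, nb_ph),
               n_cells = length(ma$cell_id))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Relative motion between germ layers
#'
#' For every mesendoderm cell and sampled window (default 10 min): the
#' difference between its own motion vector and the mean motion vector of
#' its `k` nearest epiblast neighbours, in spherical components expressed
#' as arc lengths (d_r um; r cos(phi) d_theta um; r d_phi um -- negative
#' latitude residual means animal-ward). Residuals are averaged over the
#' Mercator grid per time interval; the radial components are additionally
#' summarised as kernel-smoothed densities per interval (the radial
#' dimension is lost in the 2D maps).
#'
#' @param ts_meso,ts_epi mesendoderm / epiblast track sets.
#' @param frame a [spherical_frame()].
#' @param k number of epiblast neighbours.
#' @param window_min window duration, minutes.
#' @param neighbor_cutoff_um exclude mesendoderm cells whose nearest
#'   epiblast neighbour is farther than this (counted).
#' @param grid a [flow_grid()] for the residual maps.
#' @param n_intervals time bins for maps and densities.
#' @param stride_frames spacing of evaluated windows.
#' @return object of class `layer_residuals`: `residuals` (per cell and
#'   window), `map` (arrays `d_r`, `d_theta_um`, `d_phi_um`, `n` over grid
#'   x intervals), `radial_density` (list of [stats::density()] per
#'   interval), `n_excluded`.
#' @export
relative_layer_motion <- function(ts_meso, ts_epi,
                                  frame = spherical_frame(), k = 6L,
                                  window_min = 10,
                                  neighbor_cutoff_um = 100,
                                  grid = flow_grid(), n_intervals = 10L,
                                  stride_frames = NULL) {
  wf <- max(1L, round(window_min * 60 / ts_meso$frame_interval))
  if (is.null(stride_frames)) stride_frames <- wf
  frames <- sort(unique(ts_meso$data$frame))
  f_eval <- frames[seq(1L, max(1L, length(frames) - wf), by = stride_frames)]
  f_eval <- f_eval[f_eval + wf <= max(frames)]
  n_excluded <- 0L
  rows <- list()
  for (f0 in f_eval) {
    mm <- window_motion(ts_meso, frame, f0, f0 + wf)
    me <- window_motion(ts_epi, frame, f0, f0 + wf)
    if (is.null(mm) || is.null(me) || length(me$cell_id) < k) next
    nn <- knn_index(mm$pos, me$pos, k)
    d_first <- sqrt(rowSums((mm$pos - me$pos[nn[, 1L], , drop = FALSE])^2))
    ok <- d_first <= neighbor_cutoff_um
    n_excluded <- n_excluded + sum(!ok)
    if (!any(ok)) next
    nb_r <- rowMeans(matrix(me$d_r[nn], nrow(nn)))
    nb_th <- rowMeans(matrix(me$d_theta[nn], nrow(nn)))
    nb_ph <- rowMeans(matrix(me$d_phi[nn], nrow(nn)))
    r0 <- mm$r
    t0 <- ts_meso$data$time_hpf[match(f0, ts_meso$data$frame)]
    mp <- mercator_project(mm$theta, mm$phi, grid$phi_max)
    rows[[length(rows) + 1L]] <- data.frame(
      frame = f0, time_hpf = t0, cell_id = mm$cell_id,
      u = mp$u, v = mp$v,
      d_r = mm$d_r - nb_r,
      d_theta_um = r0 * cos(mm$phi) * wrap_angle(mm$d_theta - nb_th),
      d_phi_um = r0 * (mm$d_phi - nb_ph))[ok, , drop = FALSE]
  }
  res <- do.call(rbind, rows)
  if (is.null(res) || !nrow(res)) {
    stopf("no mesendoderm cell had an epiblast neighbourhood within the cutoff")
  }
  rownames(res) <- NULL
  t_range <- range(res$time_hpf)
  if (diff(t_range) == 0) t_range <- t_range + c(0, 1e-6)
  breaks <- seq(t_range[1L], t_range[2L], length.out = n_intervals + 1L)
  it <- findInterval(res$time_hpf, breaks, rightmost.closed = TRUE,
                     all.inside = TRUE)
  cell <- grid_cell_of(grid, res$u, res$v)
  dims <- c(grid$n_u, grid$n_v, n_intervals)
  map <- list(d_r = array(NA_real_, dims), d_theta_um = array(NA_real_, dims),
              d_phi_um = array(NA_real_, dims), n = array(0L, dims))
  key <- paste(cell$iu, cell$iv, it)
  for (kk in unique(key)) {
    sel <- key == kk
    idx <- as.integer(strsplit(kk, " ")[[1L]])
    map$d_r[idx[1L], idx[2L], idx[3L]] <- mean(res$d_r[sel])
    map$d_theta_um[idx[1L], idx[2L], idx[3L]] <- mean(res$d_theta_um[sel])
    map$d_phi_um[idx[1L], idx[2L], idx[3L]] <- mean(res$d_phi_um[sel])
    map$n[idx[1L], idx[2L], idx[3L]] <- sum(sel)
  }
  dens <- lapply(seq_len(n_intervals), function(t) {
    v <- res$d_r[it == t]
    if (length(v) >= 2L && stats::sd(v) > 0) stats::density(v) else NULL
  })
  structure(list(residuals = res, map = map, radial_density = dens,
                 interval_breaks = breaks, grid = grid,
                 n_excluded = n_excluded),
            class = "layer_residuals")
}

#' @export
print.layer_residuals <- function(x, ...) {
  cat(sprintf("<layer_residuals> %d cell-windows, %d excluded; mean (d_r, d_theta, d_phi) = (%.2f, %.2f, %.2f) um\n",
              nrow(x$residuals), x$n_excluded, mean(x$residuals$d_r),
              mean(x$residuals$d_theta_um), mean(x$residuals$d_phi_um)))
  invisible(x)
}
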