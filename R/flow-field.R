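#' Regular grid over the Mercator plane
#'
#' The spatial discretisation all flow analyses share: a `n_u` x `n_v`
#' regular grid over longitude \eqn{(-\pi, \pi]} and the Mercator latitude
#' range implied by the clamp `phi_max`.
#'
#' @param n_u,n_v grid cells along longitude / Mercator latitude.
#' @param phi_max latitude clamp defining the v extent, rad.
#' @return object of class `flow_grid` with cell edges and centres.
#' @export
flow_grid <- function(n_u = 40L, n_v = 40L, phi_max = 1.4835) {
  v_max <- log(tan(pi / 4 + phi_max / 2))
  u_breaks <- seq(-pi, pi, length.out = n_u + 1L)
  v_breaks <- seq(-v_max, v_max, length.out = n_v + 1L)
  structure(list(n_u = as.integer(n_u), n_v = as.integer(n_v),
                 phi_max = phi_max,
                 u_breaks = u_breaks, v_breaks = v_breaks,
                 u_centers = (u_breaks[-1L] + u_breaks[-(n_u + 1L)]) / 2,
                 v_centers = (v_breaks[-1L] + v_breaks[-(n_v + 1L)]) / 2),
            class = "flow_grid")
}

grid_cell_of <- function(grid, u, v) {
  iu <- findInterval(u, grid$u_breaks, rightmost.closed = TRUE,
                     all.inside = TRUE)
  iv <- findInterval(v, grid$v_breaks, rightmost.closed = TRUE,
                     all.inside = TRUE)
  inside <- u >= grid$u_breaks[1L] & u <= grid$u_breaks[grid$n_u + 1L] &
    v >= grid$v_breaks[1L] & v <= grid$v_breaks[grid$n_v + 1L]
  list(iu = iu, iv = iv, inside = inside)
}

#' Build a gridded spatio-temporal tissue flow field from tracks
#'
#' Every consecutive-frame displacement is taken in the Mercator tangent
#' plane (du = wrapped longitude change, dv = Mercator latitude change),
#' unit-normalised, and assigned to the grid cell of its start point and
#' to its time interval. The per-cell flow vector is the mean of the
#' assigned unit vectors (stored as a unit direction with the resultant
#' length, a coherence in [0, 1], carried separately); the weight is the
#' observation count. The default layout is a 40 x 40 grid and 10 time
#' intervals spanning the track-set duration.
#'
#' @param ts a [track_set()] aligned to `frame`.
#' @param frame a [spherical_frame()].
#' @param grid a [flow_grid()].
#' @param n_intervals number of time bins.
#' @param time_range `c(from, to)` hpf; default the observed range.
#' @return object of class `flow_field`: arrays `ux`, `uy` (unit direction),
#'   `coherence`, `mean_step_um`, `weight` with dim (n_u, n_v,
#'   n_intervals), the `grid`, `interval_breaks` (hpf) and `n_embryos = 1`.
#' @export
build_flow_field <- function(ts, frame = spherical_frame(),
                             grid = flow_grid(), n_intervals = 10L,
                             time_range = NULL) {
  d <- ts$data
  if (is.null(time_range)) time_range <- range(d$time_hpf)
  breaks <- seq(time_range[1L], time_range[2L], length.out = n_intervals + 1L)
  dims <- c(grid$n_u, grid$n_v, n_intervals)
  sx <- array(0, dims); sy <- array(0, dims)
  wt <- array(0L, dims); st <- array(0, dims)
  n_skipped <- 0L
  for (df in track_split(ts)) {
    if (nrow(df) < 2L) next
    sp <- to_spherical(track_positions(df), frame)
    mp <- mercator_project(sp$theta, sp$phi, grid$phi_max)
    du <- wrap_angle(diff(mp$u))
    dv <- diff(mp$v)
    len <- sqrt(du^2 + dv^2)
    step_um <- row_norms(diff(track_positions(df)))
    t0 <- df$time_hpf[-nrow(df)]
    it <- findInterval(t0, breaks, rightmost.closed = TRUE, all.inside = TRUE)
    cell <- grid_cell_of(grid, mp$u[-nrow(df)], mp$v[-nrow(df)])
    ok <- len > 0 & cell$inside & t0 >= time_range[1L] & t0 <= time_range[2L]
    n_skipped <- n_skipped + sum(!ok)
    if (!any(ok)) next
    lin <- cbind(cell$iu, cell$iv, it)[ok, , drop = FALSE]
    ux1 <- (du / len)[ok]; uy1 <- (dv / len)[ok]
    for (j in seq_len(nrow(lin))) {
      i1 <- lin[j, 1L]; i2 <- lin[j, 2L]; i3 <- lin[j, 3L]
      sx[i1, i2, i3] <- sx[i1, i2, i3] + ux1[j]
      sy[i1, i2, i3] <- sy[i1, i2, i3] + uy1[j]
      wt[i1, i2, i3] <- wt[i1, i2, i3] + 1L
      st[i1, i2, i3] <- st[i1, i2, i3] + step_um[ok][j]
    }
  }
  resultant <- sqrt(sx^2 + sy^2)
  coh <- ifelse(wt > 0, resultant / pmax(wt, 1L), NA_real_)
  ux <- ifelse(wt > 0 & resultant > 0, sx / pmax(resultant, 1e-300), NA_real_)
  uy <- ifelse(wt > 0 & resultant > 0, sy / pmax(resultant, 1e-300), NA_real_)
  structure(list(ux = ux, uy = uy, coherence = coh,
                 mean_step_um = ifelse(wt > 0, st / pmax(wt, 1L), NA_real_),
                 weight = wt, grid = grid, interval_breaks = breaks,
                 n_embryos = 1L, n_skipped = n_skipped),
            class = "flow_field")
}

#' @export
print.flow_field <- function(x, ...) {
  cat(sprintf("<flow_field> %dx%d grid, %d intervals (%.2f-%.2f hpf), %d observations, %d embryo(s)\n",
              x$grid$n_u, x$grid$n_v, length(x$interval_breaks) - 1L,
              x$interval_breaks[1L],
              x$interval_breaks[length(x$interval_breaks)],
              sum(x$weight), x$n_embryos))
  invisible(x)
}

#' Average flow fields across embryos
#'
#' Per grid cell and interval: mean of the per-embryo unit flow vectors
#' (over embryos observing that cell), renormalised; weights are summed.
#' Cells where the embryo directions cancel (zero resultant) are flagged
#' incoherent (`NA` direction, `coherence` 0).
#'
#' @param fields list of [build_flow_field()] results with identical grid
#'   and interval layout.
#' @return a `flow_field` with `n_embryos` summed.
#' @export
average_flow_fields <- function(fields) {
  if (!length(fields)) stopf("no flow fields given")
  g1 <- fields[[1L]]
  for (f in fields[-1L]) {
    if (!isTRUE(all.equal(f$grid, g1$grid)) ||
        !isTRUE(all.equal(f$interval_breaks, g1$interval_breaks))) {
      stopf("flow field layouts differ (grid or interval breaks)")
    }
  }
  dims <- dim(g1$weight)
  sx <- array(0, dims); sy <- array(0, dims)
  n_obs <- array(0L, dims); wt <- array(0L, dims)
  st <- array(0, dims)
  for (f in fields) {
    has <- f$weight > 0 & !is.na(f$ux)
    sx[has] <- sx[has] + f$ux[has]
    sy[has] <- sy[has] + f$uy[has]
    n_obs[has] <- n_obs[has] + 1L
    wt <- wt + f$weight
    st[has] <- st[has] + f$mean_step_um[has]
  }
  resultant <- sqrt(sx^2 + sy^2)
  coh <- ifelse(n_obs > 0, resultant / pmax(n_obs, 1L), NA_real_)
  ux <- ifelse(n_obs > 0 & resultant > 1e-12, sx / pmax(resultant, 1e-300),
               NA_real_)
  uy <- ifelse(n_obs > 0 & resultant > 1e-12, sy / pmax(resultant, 1e-300),
               NA_real_)
  structure(list(ux = ux, uy = uy, coherence = coh,
                 mean_step_um = ifelse(n_obs > 0, st / pmax(n_obs, 1L),
                                       NA_real_),
                 weight = wt, grid = g1$grid,
                 interval_breaks = g1$interval_breaks,
                 n_embryos = sum(vapply(fields, `[[`, integer(1), "n_embryos")),
                 n_skipped = sum(vapply(fields, function(f)
                   f$n_skipped %||% 0L, numeric(1)))),
            class = "flow_field")
}

#' Quiver plot of one interval of a flow field
#' @param x a `flow_field`.
#' @param interval time interval index.
#' @param ... passed to [graphics::plot()].
#' @export
plot.flow_field <- function(x, interval = 1L, ...) {
  g <- x$grid
  du <- diff(g$u_centers[1:2])
  graphics::plot(NA, xlim = range(g$u_breaks), ylim = range(g$v_breaks),
                 xlab = "u", ylab = "v", ...)
  for (iu in seq_len(g$n_u)) for (iv in seq_len(g$n_v)) {
    if (x$weight[iu, iv, interval] > 0 && !is.na(x$ux[iu, iv, interval])) {
      u0 <- g$u_centers[iu]; v0 <- g$v_centers[iv]
      graphics::arrows(u0, v0, u0 + 0.8 * du * x$ux[iu, iv, interval],
                       v0 + 0.8 * du * x$uy[iu, iv, interval],
                       length = 0.02, col = "grey30")
    }
  }
  invisible(x)
}
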