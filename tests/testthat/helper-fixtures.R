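# shared fixtures, all generated in code

ref_frame <- function(radius = 350) spherical_frame(radius = radius)

# small embryo so rendered stacks stay compact
small_embryo_config <- function(seed = 4, n_cells = 120, ...) {
  embryo_sim_config(n_cells = n_cells, embryo_radius = 100,
                    chorion_radius = 160, shell_band = 30,
                    t_end = 5, noise_sd = 0, seed = seed, ...)
}

# track_set from a list of position matrices (one per cell)
tracks_from_positions <- function(pos_list, frame_interval = 120,
                                  t_start = 5, layer = "epiblast") {
  rows <- lapply(seq_along(pos_list), function(i) {
    p <- as.matrix(pos_list[[i]])
    data.frame(frame = seq_len(nrow(p)),
               time_hpf = t_start + (seq_len(nrow(p)) - 1) *
                 frame_interval / 3600,
               cell_id = i, parent_id = NA, x_um = p[, 1], y_um = p[, 2],
               z_um = p[, 3], layer = layer, mezzo = 0, sox17 = 0)
  })
  track_set(do.call(rbind, rows), frame_interval = frame_interval)
}

# single-layer embryo simulation with an optional superimposed uniform
# animal-ward latitude drift (um/min), used for layer-residual scenarios
simulate_layer <- function(layer, n, seed, drift_phi_um_min = 0,
                           frame = ref_frame(), t_start = 5, t_end = 6.5,
                           noise_sd = 0.5) {
  cfg <- embryo_sim_config(
    n_cells = n, t_start = t_start, t_end = t_end, noise_sd = noise_sd,
    seed = seed, internalize_fraction = 0,
    mesendoderm_fraction = if (layer == "epiblast") 0 else 1,
    endoderm_fraction = 0, epiboly_rate = 0.2, convergence_rate = 0.05)
  sim <- simulate_embryo_tracks(cfg)
  d <- sim$tracks$data
  if (drift_phi_um_min != 0) {
    sp <- to_spherical(as.matrix(d[, c("x_um", "y_um", "z_um")]), frame)
    t_min <- (d$time_hpf - min(d$time_hpf)) * 60
    sp$phi <- sp$phi + drift_phi_um_min * t_min / sp$r
    p <- to_cartesian(sp, frame)
    d$x_um <- p[, 1]; d$y_um <- p[, 2]; d$z_um <- p[, 3]
  }
  track_set(d, frame_interval = cfg$frame_interval)
}

# uniform random points on the unit sphere
runif_sphere <- function(n) {
  z <- stats::runif(n, -1, 1)
  th <- stats::runif(n, -pi, pi)
  s <- sqrt(1 - z^2)
  cbind(s * cos(th), s * sin(th), z)
}

# brute-force saddle oracle: highest level at which `from` connects to a
# strictly higher peak through the 26-connected superlevel set
bf_saddle <- function(a, from_ijk, peaks_ijk, levels) {
  dims <- dim(a)
  higher <- peaks_ijk[a[peaks_ijk] > a[rbind(from_ijk)], , drop = FALSE]
  if (!nrow(higher)) return(-Inf)
  best <- -Inf
  for (L in sort(levels, decreasing = TRUE)) {
    if (L > a[rbind(from_ijk)]) next
    lab <- array(0L, dims)
    mask <- a >= L
    # BFS from `from`
    queue <- list(from_ijk)
    lab[rbind(from_ijk)] <- 1L
    while (length(queue)) {
      cur <- queue[[1L]]; queue <- queue[-1L]
      for (di in -1:1) for (dj in -1:1) for (dk in -1:1) {
        nb <- cur + c(di, dj, dk)
        if (any(nb < 1L) || any(nb > dims)) next
        if (mask[rbind(nb)] && lab[rbind(nb)] == 0L) {
          lab[rbind(nb)] <- 1L
          queue[[length(queue) + 1L]] <- nb
        }
      }
    }
    reached <- apply(higher, 1L, function(h) lab[rbind(h)] == 1L)
    if (any(reached)) { best <- L; break }
  }
  best
}
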