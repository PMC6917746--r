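#' Configuration for the synthetic gastrulation embryo
#'
#' Defines the study conditions the simulator generates: cells on a thin
#' spherical shell (embryo radius ~350 um inside a ~550 um chorion)
#' advected by epiboly (meridian flow from the animal toward the vegetal
#' pole) and dorsal convergence (parallel flow toward the midline at
#' longitude 0), a mesendoderm subpopulation that internalises at the
#' shield and then drifts back toward the animal pole, layer-specific
#' expression onset, positional noise and track fragmentation.
#'
#' Flow-rate profiles may be constants (rad/h) or functions of time (hpf);
#' the defaults are smooth bumps with epiboly peaking around 5-9 hpf and
#' convergence around 8-12 hpf.
#'
#' @param n_cells number of simulated cells (0 allowed).
#' @param embryo_radius,chorion_radius sphere radii, um
#'   (`embryo_radius < chorion_radius`).
#' @param shell_band radial thickness of the occupied band below the embryo
#'   surface, um.
#' @param frame_interval frame spacing, seconds.
#' @param t_start,t_end simulated time range, hpf.
#' @param epiboly_rate,convergence_rate scalar rad/h or `function(t_hpf)`;
#'   negative values reverse the flow, non-finite values are rejected.
#' @param internalize_fraction fraction of mesendoderm cells that
#'   internalise, in [0, 1].
#' @param internalize_depth radial inward step of internalising cells, um.
#' @param internalize_time onset of internalisation, hpf.
#' @param internalize_ramp_h duration of the inward radial step, h.
#' @param animal_drift_rate animal-ward meridian speed of internalised
#'   cells after the inward step, rad/h.
#' @param noise_sd per-axis Gaussian positional noise, um per frame.
#' @param mezzo_onset,sox17_onset expression onsets, hpf.
#' @param expression_tau first-order rise time of expression, h.
#' @param fragment_prob per-frame probability that a track is cut.
#' @param mesendoderm_fraction fraction of cells in the mesendoderm lineage.
#' @param endoderm_fraction fraction of the mesendoderm lineage that is
#'   endoderm.
#' @param margin_phi latitude of the blastoderm margin at `t_start`, rad.
#' @param min_spacing minimum distance between initial cell positions, um
#'   (cells are bodies, not points; 0 disables the constraint).
#' @param seed integer RNG seed; identical seed gives bit-identical output.
#' @return object of class `embryo_sim_config`.
#' @export
embryo_sim_config <- function(n_cells = 500,
                              embryo_radius = 350,
                              chorion_radius = 550,
                              shell_band = 50,
                              frame_interval = 120,
                              t_start = 4, t_end = 14,
                              epiboly_rate = default_epiboly_rate,
                              convergence_rate = default_convergence_rate,
                              internalize_fraction = 0.25,
                              internalize_depth = 30,
                              internalize_time = 6,
                              internalize_ramp_h = 0.5,
                              animal_drift_rate = 0.3,
                              noise_sd = 1,
                              mezzo_onset = 4.5,
                              sox17_onset = 6.5,
                              expression_tau = 0.5,
                              fragment_prob = 0,
                              mesendoderm_fraction = 0.4,
                              endoderm_fraction = 0.3,
                              margin_phi = -0.3,
                              min_spacing = 12,
                              seed = 1L) {
  if (!is.finite(n_cells) || n_cells < 0) stopf("n_cells must be >= 0")
  if (embryo_radius >= chorion_radius) {
    stopf("embryo_radius must be < chorion_radius")
  }
  if (internalize_fraction < 0 || internalize_fraction > 1) {
    stopf("internalize_fraction must be in [0, 1]")
  }
  if (!is.finite(frame_interval) || frame_interval <= 0) {
    stopf("frame_interval must be > 0")
  }
  if (t_end <= t_start) stopf("t_end must be > t_start")
  cfg <- list(n_cells = as.integer(n_cells), embryo_radius = embryo_radius,
              chorion_radius = chorion_radius, shell_band = shell_band,
              frame_interval = frame_interval, t_start = t_start,
              t_end = t_end,
              epiboly_rate = as_rate_fun(epiboly_rate),
              convergence_rate = as_rate_fun(convergence_rate),
              internalize_fraction = internalize_fraction,
              internalize_depth = internalize_depth,
              internalize_time = internalize_time,
              internalize_ramp_h = internalize_ramp_h,
              animal_drift_rate = animal_drift_rate,
              noise_sd = noise_sd, mezzo_onset = mezzo_onset,
              sox17_onset = sox17_onset, expression_tau = expression_tau,
              fragment_prob = fragment_prob,
              mesendoderm_fraction = mesendoderm_fraction,
              endoderm_fraction = endoderm_fraction,
              margin_phi = margin_phi, min_spacing = min_spacing,
              seed = as.integer(seed))
  class(cfg) <- "embryo_sim_config"
  cfg
}

as_rate_fun <- function(r) {
  if (is.function(r)) return(r)
  if (!is.numeric(r) || length(r) != 1L) stopf("rate must be scalar or function")
  force(r)
  function(t) rep(r, length(t))
}

#' Default epiboly rate profile (rad/h), peaking around 5-9 hpf
#' @param t time, hpf
#' @export
default_epiboly_rate <- function(t) 0.35 * exp(-((t - 7) / 2.5)^2)

#' Default convergence rate profile (rad/h), peaking around 8-12 hpf
#' @param t time, hpf
#' @export
default_convergence_rate <- function(t) 0.18 * exp(-((t - 10) / 2.5)^2)

#' Simulate ground-truth embryo tracks
#'
#' Integrates every cell on its spherical shell: latitude advances with the
#' epiboly rate (capped short of the vegetal pole), longitude shrinks toward
#' the dorsal midline with the convergence rate, radii are constant except
#' for internalising cells, which step inward by `internalize_depth` over
#' `internalize_ramp_h` starting at `internalize_time` and afterwards drift
#' animal-ward. Internalisation flags are Bernoulli(`internalize_fraction`)
#' over the mesendoderm lineage; flagged cells are seeded near the shield
#' (longitude ~0, near the margin) so the event happens where it does in the
#' embryo. Gaussian positional noise and track fragmentation apply to the
#' observed tracks only; the returned ground truth keeps the complete,
#' noise-free tracks.
#'
#' Randomness is drawn from per-cell substreams derived from
#' `config$seed` and the cell counter, so cell i's trajectory does not
#' depend on how many further cells are simulated and identical seeds give
#' bit-identical output.
#'
#' @param config an [embryo_sim_config()].
#' @return list with elements `tracks` (observed [track_set()], noisy and
#'   possibly fragmented) and `truth` (class `embryo_truth`: noise-free
#'   `tracks`, per-cell `layer` and `internalized`, per-frame `flow_params`,
#'   `fragment_map` linking observed to true cell ids, and the `config`).
#' @export
simulate_embryo_tracks <- function(config) {
  stopifnot(inherits(config, "embryo_sim_config"))
  dt_h <- config$frame_interval / 3600
  t_hpf <- seq(config$t_start, config$t_end, by = dt_h)
  nf <- length(t_hpf)
  epi_r <- config$epiboly_rate(t_hpf)
  conv_r <- config$convergence_rate(t_hpf)
  if (any(is.na(epi_r)) || any(is.na(conv_r)) ||
      any(!is.finite(epi_r)) || any(!is.finite(conv_r))) {
    stopf("flow rate profiles must be finite over the simulated time range")
  }
  frame0 <- spherical_frame(center = c(0, 0, 0), radius = config$embryo_radius)
  flow_params <- data.frame(time_hpf = t_hpf, epiboly_rate = epi_r,
                            convergence_rate = conv_r)

  n <- config$n_cells
  if (n == 0L) {
    empty <- track_set(data.frame(frame = integer(), time_hpf = numeric(),
                                  cell_id = integer(), parent_id = integer(),
                                  x_um = numeric(), y_um = numeric(),
                                  z_um = numeric(), layer = character(),
                                  mezzo = numeric(), sox17 = numeric()),
                       frame_interval = config$frame_interval)
    truth <- structure(list(tracks = empty, layer = character(0),
                            internalized = logical(0),
                            flow_params = flow_params,
                            fragment_map = data.frame(obs_id = integer(),
                                                      true_id = integer()),
                            config = config),
                       class = "embryo_truth")
    return(list(tracks = empty, truth = truth))
  }

  phi_cap <- 1.45
  layer <- character(n)
  internal <- logical(n)
  obs_rows <- vector("list", n)
  true_rows <- vector("list", n)
  frag_map <- vector("list", n)
  next_extra_id <- n + 1L

  placed <- matrix(numeric(0), 0L, 3L)
  for (i in seq_len(n)) {
    cell <- with_substream(config$seed, i, {
      u_layer <- stats::runif(2L)
      lay <- if (u_layer[1L] < config$mesendoderm_fraction) {
        if (u_layer[2L] < config$endoderm_fraction) "endoderm" else "mesendoderm"
      } else "epiblast"
      meso <- lay != "epiblast"
      flag <- meso && stats::runif(1L) < config$internalize_fraction
      # rejection-sample the start position against already placed cells
      # (draws come from this cell's substream; dependence is only on
      # earlier cells, so adding cells never perturbs existing ones)
      phi0 <- th0 <- r0 <- NA_real_
      for (try in 1:60) {
        if (flag) {
          phi_c <- stats::runif(1L, config$margin_phi - 0.25,
                                config$margin_phi)
          th_c <- clamp(stats::rnorm(1L, 0, pi / 8), -pi + 1e-6, pi)
        } else {
          s <- stats::runif(1L, -1, sin(config$margin_phi))
          phi_c <- asin(s)
          th_c <- stats::runif(1L, -pi, pi)
        }
        r_c <- if (meso) {
          stats::runif(1L, config$embryo_radius - config$shell_band,
                       config$embryo_radius - config$shell_band / 2)
        } else {
          stats::runif(1L, config$embryo_radius - config$shell_band / 2,
                       config$embryo_radius)
        }
        phi0 <- phi_c; th0 <- th_c; r0 <- r_c
        if (config$min_spacing <= 0 || !nrow(placed)) break
        p_c <- to_cartesian(c(r_c, th_c, phi_c), frame0)
        if (min(row_norms(sweep(placed, 2L, p_c))) >= config$min_spacing) break
      }
      noise <- matrix(stats::rnorm(3L * nf, 0, config$noise_sd), ncol = 3L)
      cuts <- stats::runif(nf) < config$fragment_prob
      list(lay = lay, flag = flag, phi0 = phi0, th0 = th0, r0 = r0,
           noise = noise, cuts = cuts)
    })
    placed <- rbind(placed,
                    to_cartesian(c(cell$r0, cell$th0, cell$phi0), frame0))
    layer[i] <- cell$lay
    internal[i] <- cell$flag

    r <- numeric(nf); th <- numeric(nf); ph <- numeric(nf)
    r[1L] <- cell$r0; th[1L] <- cell$th0; ph[1L] <- cell$phi0
    t_ramp0 <- config$internalize_time
    t_ramp1 <- t_ramp0 + config$internalize_ramp_h
    for (k in seq_len(nf - 1L)) {
      tk <- t_hpf[k]
      dr <- 0
      dphi <- epi_r[k] * dt_h
      if (cell$flag && tk >= t_ramp0) {
        if (tk < t_ramp1) {
          dr <- -config$internalize_depth * dt_h / config$internalize_ramp_h
        } else {
          dphi <- -config$animal_drift_rate * dt_h
        }
      }
      r[k + 1L] <- r[k] + dr
      ph[k + 1L] <- clamp(ph[k] + dphi, -phi_cap, phi_cap)
      shrink <- abs(conv_r[k]) * dt_h
      th_new <- sign(th[k]) * max(abs(th[k]) - shrink, 0)
      # negative convergence rates push away from the midline instead
      if (conv_r[k] < 0) th_new <- wrap_angle(th[k] + sign(th[k]) * shrink)
      th[k + 1L] <- th_new
    }

    mezzo <- if (layer[i] == "epiblast") rep(0, nf) else {
      expression_rise(t_hpf, config$mezzo_onset, config$expression_tau)
    }
    sox17 <- if (layer[i] == "endoderm") {
      expression_rise(t_hpf, config$sox17_onset, config$expression_tau)
    } else rep(0, nf)

    p_true <- to_cartesian(data.frame(r = r, theta = th, phi = ph), frame0)
    true_rows[[i]] <- data.frame(frame = seq_len(nf), time_hpf = t_hpf,
                                 cell_id = i, parent_id = NA_integer_,
                                 x_um = p_true[, 1L], y_um = p_true[, 2L],
                                 z_um = p_true[, 3L], layer = layer[i],
                                 mezzo = mezzo, sox17 = sox17)
    p_obs <- p_true + cell$noise

    # fragmentation: a cut after frame k starts a new observed tracklet
    cut_after <- which(cell$cuts[-nf])
    bounds <- c(0L, cut_after, nf)
    ids <- integer(nf)
    for (f in seq_len(length(bounds) - 1L)) {
      seg <- (bounds[f] + 1L):bounds[f + 1L]
      id <- if (f == 1L) i else {
        id2 <- next_extra_id; next_extra_id <- next_extra_id + 1L; id2
      }
      ids[seg] <- id
    }
    obs_rows[[i]] <- data.frame(frame = seq_len(nf), time_hpf = t_hpf,
                                cell_id = ids, parent_id = NA_integer_,
                                x_um = p_obs[, 1L], y_um = p_obs[, 2L],
                                z_um = p_obs[, 3L], layer = layer[i],
                                mezzo = mezzo, sox17 = sox17)
    frag_map[[i]] <- data.frame(obs_id = unique(ids), true_id = i)
  }

  obs <- do.call(rbind, obs_rows)
  tru <- do.call(rbind, true_rows)
  tracks <- track_set(obs, frame_interval = config$frame_interval)
  truth <- structure(list(
    tracks = track_set(tru, frame_interval = config$frame_interval),
    layer = layer, internalized = internal, flow_params = flow_params,
    fragment_map = do.call(rbind, frag_map), config = config),
    class = "embryo_truth")
  list(tracks = tracks, truth = truth)
}

# first-order expression rise after onset, in [0, 1)
expression_rise <- function(t, onset, tau) {
  pmax(0, 1 - exp(-(pmax(t - onset, 0)) / tau)) * (t >= onset)
}

#' @export
print.embryo_truth <- function(x, ...) {
  cat(sprintf("<embryo_truth> %d cells (%s), %d internalized\n",
              length(x$layer),
              paste(sprintf("%s=%d", names(table(x$layer)), table(x$layer)),
                    collapse = " "),
              sum(x$internalized)))
  invisible(x)
}

#' Write ground truth as sidecar JSON
#' @param truth an `embryo_truth` object.
#' @param path output JSON path.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(list(layer = truth$layer,
                            internalized = truth$internalized,
                            flow_params = truth$flow_params,
                            fragment_map = truth$fragment_map,
                            seed = truth$config$seed),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Render fluorescence channel stacks from cell positions
#'
#' Emulates the three transgenic channels at one frame: channel 3 nuclear
#' blobs at all cell positions (ubiquitous histone label), channel 2 broader
#' cytoplasmic blobs at mesendoderm and endoderm positions, channel 1
#' nuclear blobs at endoderm positions. Blobs are isotropic Gaussians;
#' optional background offset and Poisson-like noise.
#'
#' @param tracks a [track_set()] whose `layer` column drives the channel
#'   rules.
#' @param frame_idx frame index to render.
#' @param voxel_size voxel edge, um.
#' @param shape integer length-3 stack dimensions, voxels; must contain all
#'   cells with a 3-sigma margin (the offending dimension is named
#'   otherwise).
#' @param nuclear_sigma,cyto_sigma blob standard deviations, um.
#' @param amplitude peak blob intensity.
#' @param background additive offset.
#' @param noise if TRUE add Gaussian noise with variance equal to the local
#'   mean (Poisson-like).
#' @return named list of three [voxel_stack()]s: `ch1` (endoderm nuclei),
#'   `ch2` (mesendoderm + endoderm cytoplasm), `ch3` (all nuclei).
#' @export
render_channel_stacks <- function(tracks, frame_idx, voxel_size = 4,
                                  shape = c(96L, 96L, 96L),
                                  nuclear_sigma = 4, cyto_sigma = 8,
                                  amplitude = 1000, background = 0,
                                  noise = FALSE) {
  d <- tracks$data[tracks$data$frame == frame_idx, , drop = FALSE]
  if (!nrow(d)) stopf("frame %s has no cells", frame_idx)
  shape <- as.integer(shape)
  template <- voxel_stack(array(0, shape), voxel_size = voxel_size)
  pos <- track_positions(d)
  check_fits(pos, template, 3 * cyto_sigma)
  meso <- d$layer %in% c("mesendoderm", "endoderm")
  endo <- d$layer == "endoderm"
  ch3 <- add_blobs(array(background, shape), pos, template, nuclear_sigma,
                   amplitude)
  ch2 <- add_blobs(array(background, shape),
                   pos[meso, , drop = FALSE], template, cyto_sigma, amplitude)
  ch1 <- add_blobs(array(background, shape),
                   pos[endo, , drop = FALSE], template, nuclear_sigma,
                   amplitude)
  out <- list(ch1 = ch1, ch2 = ch2, ch3 = ch3)
  out <- lapply(out, function(a) {
    if (noise) a <- pmax(a + stats::rnorm(length(a), 0, sqrt(pmax(a, 1))), 0)
    a
  })
  list(ch1 = voxel_stack(out$ch1, voxel_size, "sox17 (endoderm, nuclear)"),
       ch2 = voxel_stack(out$ch2, voxel_size, "mezzo (mesendoderm, cytoplasmic)"),
       ch3 = voxel_stack(out$ch3, voxel_size, "histone (all nuclei)"))
}

check_fits <- function(pos, template, margin_um) {
  if (!nrow(pos)) return(invisible(TRUE))
  v <- world_to_voxel(pos, template)
  m <- margin_um / stack_voxel_size(template)
  dims <- dim(template)
  ax <- c("x", "y", "z")
  for (j in 1:3) {
    if (any(v[, j] - m < 1) || any(v[, j] + m > dims[j])) {
      stopf("stack shape too small to contain the embryo in dimension %s",
            ax[j])
    }
  }
  invisible(TRUE)
}

# add separable Gaussian blobs at world positions (vectorised per cell)
add_blobs <- function(a, pos, template, sigma_um, amplitude) {
  if (!nrow(pos)) return(a)
  vs <- stack_voxel_size(template)
  sig <- sigma_um / vs
  half <- ceiling(3 * sig)
  v <- world_to_voxel(pos, template)
  dims <- dim(a)
  for (i in seq_len(nrow(v))) {
    c0 <- v[i, ]
    ix <- max(1L, floor(c0[1L] - half)):min(dims[1L], ceiling(c0[1L] + half))
    iy <- max(1L, floor(c0[2L] - half)):min(dims[2L], ceiling(c0[2L] + half))
    iz <- max(1L, floor(c0[3L] - half)):min(dims[3L], ceiling(c0[3L] + half))
    gx <- exp(-((ix - c0[1L])^2) / (2 * sig^2))
    gy <- exp(-((iy - c0[2L])^2) / (2 * sig^2))
    gz <- exp(-((iz - c0[3L])^2) / (2 * sig^2))
    blob <- amplitude * outer(outer(gx, gy), gz)
    a[ix, iy, iz] <- a[ix, iy, iz] + blob
  }
  a
}

#' Render a synthetic transmission stack with two spherical shells
#'
#' Produces the input the two-sphere fit expects: two noisy spherical
#' surfaces of elevated intensity (embryo and chorion) on a flat
#' background, mimicking the in-focus edges of a transmission image after
#' focus filtering.
#'
#' @param config an [embryo_sim_config()] providing the two radii.
#' @param voxel_size voxel edge, um.
#' @param shape stack dimensions, voxels; defaults to the smallest cube
#'   holding the chorion. Radii at or beyond half the minimum physical
#'   extent are an error.
#' @param shell_width Gaussian radial width of each shell, um.
#' @param amplitude shell peak intensity above background.
#' @param background flat offset.
#' @param noise_sd additive Gaussian noise sd (0 = noise free).
#' @return a [voxel_stack()].
#' @export
render_transmission_stack <- function(config, voxel_size = 4, shape = NULL,
                                      shell_width = 6, amplitude = 1000,
                                      background = 50, noise_sd = 0) {
  r1 <- config$embryo_radius; r2 <- config$chorion_radius
  if (is.null(shape)) {
    shape <- rep(2L * ceiling((r2 + 4 * shell_width) / voxel_size) + 1L, 3L)
  }
  shape <- as.integer(shape)
  half_extent <- min(shape) * voxel_size / 2
  if (max(r1, r2) >= half_extent) {
    stopf("sphere radius %g um does not fit: half the minimum stack extent is %g um",
          max(r1, r2), half_extent)
  }
  ax <- lapply(shape, function(n) (seq_len(n) - (n + 1) / 2) * voxel_size)
  d2 <- outer(outer(ax[[1L]]^2, ax[[2L]]^2, `+`), ax[[3L]]^2, `+`)
  dist <- sqrt(d2)
  a <- background +
    amplitude * (exp(-(dist - r1)^2 / (2 * shell_width^2)) +
                   exp(-(dist - r2)^2 / (2 * shell_width^2)))
  if (noise_sd > 0) a <- a + stats::rnorm(length(a), 0, noise_sd)
  voxel_stack(a, voxel_size = voxel_size, channel = "transmission")
}
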