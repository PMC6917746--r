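test_that("straightness index matches its closed forms exactly", {
  expect_equal(straightness_index(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0))),
               1, tolerance = 1e-12)
  expect_equal(straightness_index(rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0))),
               sqrt(2) / 2, tolerance = 1e-12)
  square <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0), c(0, 0, 0))
  expect_equal(straightness_index(square), 0, tolerance = 1e-12)
  expect_true(is.na(straightness_index(rbind(c(1, 1, 1), c(1, 1, 1)))))
  expect_error(straightness_index(rbind(c(0, 0, 0))), "at least 2")
})

test_that("straightness is invariant under rigid transforms and scaling", {
  set.seed(31)
  for (i in 1:20) {
    p <- apply(matrix(rnorm(30), ncol = 3), 2, cumsum)
    si <- straightness_index(p)
    R <- rotation_about_axis(rnorm(3), runif(1, -pi, pi))
    s <- runif(1, 0.1, 10)
    q <- s * p %*% t(R) + matrix(rnorm(3, sd = 50), nrow(p), 3, byrow = TRUE)
    expect_equal(straightness_index(q), si, tolerance = 1e-9)
  }
})

test_that("per-track straightness flags stationary tracks and keeps the rest", {
  ts <- tracks_from_positions(list(
    rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)),
    rbind(c(5, 5, 5), c(5, 5, 5), c(5, 5, 5))))
  out <- track_straightness(ts)
  expect_equal(out$si[1], 1)
  expect_true(is.na(out$si[2]))
  expect_equal(attr(out, "n_undefined"), 1L)
})

test_that("SI windows are non-overlapping, start-aligned, ten frames by default", {
  expect_equal(formals(si_position_analysis)$window_frames, 10L)
  fr <- ref_frame()
  p <- cbind(seq(0, 48, length.out = 25), 100, 200)   # straight 3D line
  ts <- tracks_from_positions(list(p))
  res <- si_position_analysis(ts, fr, window_frames = 10L)
  expect_equal(nrow(res$points), 2L)   # 25 frames -> 2 full windows
  expect_equal(res$points$window, 1:2)
  expect_equal(res$points$si, c(1, 1), tolerance = 1e-9)
})

test_that("prediction ellipses scale by the chi-square quantile and cover 90%", {
  set.seed(32)
  n <- 1e5
  xy <- cbind(rnorm(n), rnorm(n))
  ell <- prediction_ellipse(xy, level = 0.90)
  target <- sqrt(qchisq(0.90, 2))
  expect_equal(ell$radius, target, tolerance = 1e-12)
  expect_equal(target, 2.146, tolerance = 1e-3)
  # standard normal sample: semi-axes approach the quantile radius
  expect_lt(max(abs(ell$semi_axes / target - 1)), 0.01)
  # empirical coverage on held-out draws
  held <- cbind(rnorm(n), rnorm(n))
  cov_emp <- mean(in_ellipse(ell, held))
  expect_lt(abs(cov_emp - 0.90), 3 * sqrt(0.9 * 0.1 / n))
})

test_that("layers with too few windows get no ellipse but are flagged", {
  fr <- ref_frame()
  p <- to_cartesian(data.frame(r = rep(350, 10),
                               theta = seq(0, 0.1, length.out = 10),
                               phi = rep(0, 10)), fr)
  ts <- tracks_from_positions(list(p), layer = "endoderm")
  res <- si_position_analysis(ts, fr)
  expect_true("endoderm" %in% res$skipped)
  expect_null(res$ellipses$endoderm)
})

test_that("relative cell counts are exact fractions summing to one", {
  d <- rbind(
    data.frame(frame = 1, time_hpf = 5, cell_id = 1:20, parent_id = NA,
               x_um = 0, y_um = 0, z_um = 1:20,
               layer = rep(c("epiblast", "mesendoderm"), each = 10),
               mezzo = 0, sox17 = 0))
  ts <- track_set(d)
  cc <- relative_cell_counts(ts)
  expect_equal(cc$epiblast, 0.5)
  expect_equal(cc$mesendoderm, 0.5)
  expect_equal(cc$endoderm, 0)
  sim <- simulate_embryo_tracks(embryo_sim_config(n_cells = 40, t_end = 6,
                                                  seed = 33))
  cc2 <- relative_cell_counts(sim$tracks)
  expect_true(all(abs(cc2$epiblast + cc2$mesendoderm + cc2$endoderm - 1) <
                    1e-12))
})

test_that("mean radial position is normalised by the reference layer", {
  fr <- ref_frame()
  mk <- function(r, layer, id0) {
    p <- to_cartesian(data.frame(r = rep(r, 5),
                                 theta = seq(0.1, 0.2, length.out = 5),
                                 phi = 0.1), fr)
    data.frame(frame = 1:5, time_hpf = 5, cell_id = id0, parent_id = NA,
               x_um = p[, 1], y_um = p[, 2], z_um = p[, 3], layer = layer,
               mezzo = 0, sox17 = 0)
  }
  ts <- track_set(rbind(mk(350, "epiblast", 1), mk(340, "mesendoderm", 2)))
  out <- mean_radial_position(ts, fr, reference = "mesendoderm")
  expect_equal(out$rel_r[out$layer == "mesendoderm"], rep(1, 5))
  expect_equal(out$rel_r[out$layer == "epiblast"], rep(350 / 340, 5),
               tolerance = 1e-9)
})

test_that("internalization lowers the mesendoderm mean radius over its window", {
  cfg <- embryo_sim_config(n_cells = 150, t_start = 5, t_end = 8,
                           noise_sd = 0, seed = 34,
                           internalize_fraction = 0.6,
                           internalize_time = 6, internalize_ramp_h = 1)
  sim <- simulate_embryo_tracks(cfg)
  out <- mean_radial_position(sim$tracks, ref_frame())
  meso <- out[out$layer == "mesendoderm", ]
  t_hpf <- sort(unique(sim$tracks$data$time_hpf))
  ramp <- meso$mean_r[t_hpf >= 6 & t_hpf <= 7]
  expect_true(all(diff(ramp) < 0))
})

test_that("radius/latitude change recovers constant drifts from 10-minute pieces", {
  expect_equal(formals(radius_latitude_change)$piece_minutes, 10)
  fr <- ref_frame()
  # stationary track
  p0 <- matrix(rep(to_cartesian(c(350, 0.3, 0.1), fr), each = 12), ncol = 3)
  # radial drift -2 um/min at 2-minute frames
  r_t <- 350 - 2 * 2 * (0:11)
  p1 <- to_cartesian(data.frame(r = r_t, theta = 0.3, phi = 0.1), fr)
  ts <- tracks_from_positions(list(p0, p1))
  out <- radius_latitude_change(ts, fr)
  expect_equal(out$mean_dr[1], 0)
  expect_equal(out$mean_dphi[1], 0)
  expect_equal(out$mean_dr[2], -20, tolerance = 1e-9)
  # short tracks are excluded and counted
  ts_short <- tracks_from_positions(list(p0[1:3, ]))
  out_s <- radius_latitude_change(ts_short, fr)
  expect_equal(attr(out_s, "n_excluded"), 1L)
})

test_that("time reversal flips the sign of mean radial and latitude changes", {
  set.seed(35)
  fr <- ref_frame()
  p <- to_cartesian(data.frame(r = 350 + cumsum(rnorm(24)),
                               theta = 0.2, phi = cumsum(rnorm(24, sd = 0.01))),
                    fr)
  fwd <- radius_latitude_change(tracks_from_positions(list(p)), fr)
  rev <- radius_latitude_change(tracks_from_positions(list(p[24:1, ])), fr)
  expect_equal(fwd$mean_dr, -rev$mean_dr, tolerance = 1e-9)
  expect_equal(fwd$mean_dphi, -rev$mean_dphi, tolerance = 1e-9)
})

test_that("region filtering retains exactly the tracks a brute-force recount keeps", {
  expect_equal(eval(formals(filter_tracks_region)$theta_range),
               c(-pi / 8, pi / 8))
  fr <- ref_frame()
  set.seed(36)
  pos <- lapply(1:100, function(i) {
    th0 <- runif(1, -pi, pi)
    to_cartesian(data.frame(r = 350, theta = th0 + seq(0, 0.05, length.out = 8),
                            phi = runif(1, -1, 1)), fr)
  })
  ts <- tracks_from_positions(pos)
  out <- filter_tracks_region(ts, fr)
  # oracle: recount with an independent predicate evaluation
  kept_oracle <- sum(vapply(pos, function(p) {
    th <- to_spherical(p, fr)$theta
    all(th >= -pi / 8 & th <= pi / 8)
  }, logical(1)))
  expect_equal(length(unique(out$data$cell_id)), kept_oracle)

  # a track at theta = pi is excluded
  far <- tracks_from_positions(list(to_cartesian(
    data.frame(r = rep(350, 4), theta = pi, phi = 0.2), fr)))
  expect_equal(nrow(filter_tracks_region(far, fr)$data), 0L)
})

test_that("completeness filtering drops tracks that do not span the window", {
  fr <- ref_frame()
  p_full <- to_cartesian(data.frame(r = rep(350, 10), theta = 0, phi = 0.1),
                         fr)
  full <- data.frame(frame = 1:10, time_hpf = seq(5, 5.3, length.out = 10),
                     cell_id = 1, parent_id = NA, x_um = p_full[, 1],
                     y_um = p_full[, 2], z_um = p_full[, 3],
                     layer = "epiblast", mezzo = 0, sox17 = 0)
  part <- full[1:4, ]; part$cell_id <- 2
  ts <- track_set(rbind(full, part))
  out <- filter_tracks_region(ts, fr, time_range = c(5, 5.3),
                              completeness = "full")
  expect_equal(unique(out$data$cell_id), 1)
  out2 <- filter_tracks_region(ts, fr, time_range = c(5, 5.3),
                               completeness = "any")
  expect_equal(sort(unique(out2$data$cell_id)), c(1, 2))
})

test_that("latitude-profile clustering separates programmed motion modes", {
  fr <- ref_frame()
  cfg <- embryo_sim_config(n_cells = 200, t_start = 4.5, t_end = 7,
                           noise_sd = 1, seed = 37,
                           internalize_fraction = 0.5,
                           mesendoderm_fraction = 1, endoderm_fraction = 0,
                           internalize_time = 5.2, epiboly_rate = 0.25,
                           convergence_rate = 0.05)
  sim <- simulate_embryo_tracks(cfg)
  d1 <- sim$tracks$data[sim$tracks$data$frame == 1, ]
  phi0 <- to_spherical(as.matrix(d1[, c("x_um", "y_um", "z_um")]), fr)$phi
  keep <- d1$cell_id[phi0 > -0.6]
  sub <- track_set(sim$tracks$data[sim$tracks$data$cell_id %in% keep, ])
  cl <- cluster_latitude_profiles(sub, fr, k = 2)
  flags <- sim$truth$internalized[keep]
  lab <- cl$labels[as.character(keep)]
  agree <- max(mean((lab == 1) == flags), mean((lab == 2) == flags))
  expect_gte(agree, 0.95)
  # the direction-reversing cluster is the internalising one
  expect_false(is.na(cl$reversing_cluster))
  expect_gt(mean(flags[lab == cl$reversing_cluster]), 0.5)
})

test_that("clustering limiting cases: k = 1 centroid, duplicates, k > n", {
  fr <- ref_frame()
  p1 <- to_cartesian(data.frame(r = rep(350, 6),
                                theta = seq(0, 0.1, length.out = 6),
                                phi = seq(-0.3, 0, length.out = 6)), fr)
  p2 <- p1 + 5
  ts <- tracks_from_positions(list(p1, p2))
  cl1 <- cluster_latitude_profiles(ts, fr, k = 1)
  mean_pos <- (p1 + p2) / 2
  expect_equal(as.matrix(cl1$centroid_tracks[[1]][, c("x_um", "y_um", "z_um")]),
               mean_pos, tolerance = 1e-9, ignore_attr = TRUE)

  dup <- tracks_from_positions(list(p1, p1, p2, p2))
  cl2 <- cluster_latitude_profiles(dup, fr, k = 2)
  expect_equal(sort(cl2$sizes), c(2, 2))
  within_var <- sum(vapply(1:2, function(cc) {
    sum(scale(cl2$profiles[cl2$labels == cc, ], scale = FALSE)^2)
  }, numeric(1)))
  expect_lt(within_var, 1e-18)

  expect_error(cluster_latitude_profiles(ts, fr, k = 5), "exceeds")
})

test_that("fragment linking reconnects simulated tracks and respects its limits", {
  cfg <- embryo_sim_config(n_cells = 100, t_start = 5, t_end = 7,
                           noise_sd = 0.5, seed = 38, fragment_prob = 0.02,
                           internalize_fraction = 0)
  sim <- simulate_embryo_tracks(cfg)
  agg <- aggregate_long_tracks(sim$tracks, gap_frames = 3, link_radius = 15)
  links <- attr(agg, "links")
  expect_gt(nrow(links), 10)
  fm <- sim$truth$fragment_map
  true_of <- function(id) fm$true_id[match(as.numeric(id), fm$obs_id)]
  expect_gte(mean(true_of(links$from_id) == true_of(links$to_id)), 0.90)

  # unfragmented input passes through unchanged
  cfg0 <- embryo_sim_config(n_cells = 20, t_end = 5.5, seed = 39)
  sim0 <- simulate_embryo_tracks(cfg0)
  agg0 <- aggregate_long_tracks(sim0$tracks)
  expect_equal(agg0$data, sim0$tracks$data)
  expect_equal(nrow(attr(agg0, "links")), 0L)

  # zero link radius: nothing is linked
  agg_z <- aggregate_long_tracks(sim$tracks, link_radius = 0)
  expect_equal(nrow(attr(agg_z, "links")), 0L)
  expect_equal(length(unique(agg_z$data$cell_id)),
               length(unique(sim$tracks$data$cell_id)))
})

test_that("track CSV round trip preserves the table", {
  sim <- simulate_embryo_tracks(embryo_sim_config(n_cells = 10, t_end = 5,
                                                  seed = 40))
  path <- tempfile(fileext = ".csv")
  write_tracks_csv(sim$tracks, path)
  back <- read_tracks_csv(path)
  expect_equal(back$data$x_um, sim$tracks$data$x_um, tolerance = 1e-12)
  expect_equal(back$data$cell_id, sim$tracks$data$cell_id)
  expect_equal(back$data$layer, sim$tracks$data$layer)
})
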