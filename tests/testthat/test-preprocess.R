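test_that("difference-of-Gaussian filter kills constants and keeps impulse structure", {
  const <- voxel_stack(array(7, c(16L, 16L, 4L)), voxel_size = 2)
  out <- dog_filter(const, sigma = 1)
  expect_lt(max(out), 1e-9)

  h <- 40
  a <- array(0, c(21L, 21L, 3L))
  a[11L, 11L, 2L] <- h
  out <- dog_filter(voxel_stack(a, voxel_size = 2), sigma = 1)
  # oracle: direct plane-wise convolution with a discrete Gaussian kernel
  half <- 6L
  g1 <- exp(-((-half):half)^2 / 2)
  K <- outer(g1, g1); K <- K / sum(K)
  expected_center <- h * (1 - K[half + 1L, half + 1L])
  expect_equal(out[11L, 11L, 2L], expected_center, tolerance = 1e-3)
  # off-impulse voxels carry |{-G_sigma}| scaled by h
  expect_equal(out[12L, 11L, 2L], h * K[half + 2L, half + 1L],
               tolerance = 1e-3)
  # untouched planes stay zero, output is non-negative
  expect_equal(max(out[, , 1L]), 0)
  expect_gte(min(out), 0)
  expect_error(dog_filter(const, sigma = 0), "sigma")
  expect_equal(formals(dog_filter)$sigma, 1)
})

test_that("the 3x3 median network matches a brute-force plane-wise median", {
  set.seed(21)
  a <- array(runif(14 * 13 * 3), c(14L, 13L, 3L))
  fast <- gastruflow:::median3x3(a)
  slow <- a
  for (k in 1:3) for (i in 1:14) for (j in 1:13) {
    ii <- max(1, i - 1):min(14, i + 1)
    jj <- max(1, j - 1):min(13, j + 1)
    # border replication: pad by repeating edge rows/columns
    vals <- c()
    for (di in -1:1) for (dj in -1:1) {
      vals <- c(vals, a[min(max(i + di, 1), 14), min(max(j + dj, 1), 13), k])
    }
    slow[i, j, k] <- stats::median(vals)
  }
  expect_equal(unclass(fast), slow)
})

test_that("nucleus detection applies the saddle-prominence rule", {
  # two blobs, peaks 200 and 210, ridge saddle 190: separation 20 < 30, so
  # only the higher peak survives
  a <- array(0, c(30L, 9L, 3L))
  x <- seq_len(30)
  profile <- 200 * exp(-(x - 8)^2 / 8) + 210 * exp(-(x - 22)^2 / 8)
  profile <- pmax(profile, 190 * (x > 8 & x < 22))
  a[, 5L, 2L] <- profile
  st <- voxel_stack(a, voxel_size = 1)
  det <- detect_nuclei(st, sigma = 0, threshold = 150, min_prominence = 30)
  expect_equal(nrow(det), 1L)
  expect_equal(det$intensity, 210)
  # with a permissive prominence both peaks are kept
  det2 <- detect_nuclei(st, sigma = 0, threshold = 150, min_prominence = 10)
  expect_equal(nrow(det2), 2L)

  # isolated blob of height 200 on zero background: exactly one detection
  # at the blob centre
  b <- array(0, c(15L, 15L, 7L))
  ctr <- c(8L, 8L, 4L)
  for (i in 1:15) for (j in 1:15) for (k in 1:7) {
    b[i, j, k] <- 200 * exp(-sum((c(i, j, k) - ctr)^2) / 6)
  }
  stb <- voxel_stack(b, voxel_size = 1)
  detb <- detect_nuclei(stb, sigma = 1, threshold = 150, min_prominence = 30)
  expect_equal(nrow(detb), 1L)
  vox <- gastruflow:::world_to_voxel(
    as.matrix(detb[, c("x_um", "y_um", "z_um")]), stb)
  expect_lt(max(abs(vox - matrix(ctr, 1))), 1 + 1e-9)
  expect_equal(formals(detect_nuclei)$threshold, 150)
  expect_equal(formals(detect_nuclei)$min_prominence, 30)
})

test_that("prominence decisions match a brute-force superlevel flood on random blob fields", {
  set.seed(22)
  for (rep in 1:4) {
    a <- array(0, c(24L, 24L, 3L))
    n_blob <- 4L
    ctrs <- cbind(sample(4:21, n_blob), sample(4:21, n_blob),
                  sample(1:3, n_blob, replace = TRUE))
    hts <- runif(n_blob, 160, 260)
    for (bi in seq_len(n_blob)) {
      for (i in 1:24) for (j in 1:24) {
        a[i, j, ctrs[bi, 3]] <- max(a[i, j, ctrs[bi, 3]],
                                    hts[bi] * exp(-sum((c(i, j) -
                                                          ctrs[bi, 1:2])^2) / 10))
      }
    }
    st <- voxel_stack(a, voxel_size = 1)
    det <- detect_nuclei(st, sigma = 0, threshold = 150, min_prominence = 30)
    # oracle: recompute the decision per raw local maximum
    peaks <- gastruflow:::local_maxima_3d(a, 150)
    levels <- sort(unique(round(a[a >= 120], 3)), decreasing = TRUE)
    keep <- logical(nrow(peaks))
    for (pi in seq_len(nrow(peaks))) {
      sad <- bf_saddle(a, unlist(peaks[pi, c("i", "j", "k")]),
                       as.matrix(peaks[, c("i", "j", "k")]), levels)
      keep[pi] <- peaks$value[pi] - sad >= 30
    }
    expect_equal(nrow(det), sum(keep))
  }
})

test_that("ICP recovers identity, known transforms, and resists outliers", {
  set.seed(23)
  P <- matrix(rnorm(120, sd = 120), ncol = 3)
  id <- rigid_register(P, P)
  expect_equal(id$R, diag(3), tolerance = 1e-9)
  expect_equal(id$t, c(0, 0, 0), tolerance = 1e-9)
  expect_lt(id$rms, 1e-9)

  R <- rotation_about_axis(rnorm(3), 10 * pi / 180)
  tr <- c(5, 0, 0)
  Q <- P %*% t(R) + matrix(tr, nrow(P), 3, byrow = TRUE)
  fit <- rigid_register(P, Q)
  ang_err <- acos(pmin(1, (sum(diag(t(fit$R) %*% R)) - 1) / 2))
  expect_lt(ang_err, 1e-3)
  expect_lt(sqrt(sum((fit$t - tr)^2)), 1e-2)

  # 20% outliers with trimming
  Qo <- Q
  out_idx <- 1:8
  Qo[out_idx, ] <- Qo[out_idx, ] + matrix(runif(24, 100, 300), 8)
  fit2 <- rigid_register(P, Qo, trim = 0.25)
  ang_err2 <- acos(pmin(1, (sum(diag(t(fit2$R) %*% R)) - 1) / 2))
  expect_lt(ang_err2, 0.5 * pi / 180)

  line <- cbind(1:10, 2 * (1:10), -1 * (1:10))
  expect_error(rigid_register(line, P), "rank deficient")
})

test_that("two-sphere EM fit recovers synthetic shells with a monotone objective", {
  cfg <- embryo_sim_config()
  stack <- render_transmission_stack(cfg, voxel_size = 8)
  fit <- fit_two_spheres(stack)
  expect_true(fit$embryo$converged)
  expect_true(fit$chorion$converged)
  expect_lt(abs(fit$embryo$radius - 350), 3.5)
  expect_lt(abs(fit$chorion$radius - 550), 5.5)
  expect_lt(max(abs(fit$embryo$center)), 8)
  expect_true(all(diff(fit$objective) <= 1e-6 * fit$objective[1]))
  expect_equal(eval(formals(fit_two_spheres)$init_radii), c(350, 550))
})

test_that("degenerate sphere-fit inputs are flagged, not silently fitted", {
  cfg1 <- embryo_sim_config(embryo_radius = 100, chorion_radius = 500)
  # single shell: render only one surface by making the chorion invisible
  one <- render_transmission_stack(
    embryo_sim_config(embryo_radius = 100, chorion_radius = 430),
    voxel_size = 8, shape = c(112L, 112L, 112L), shell_width = 5,
    background = 0)
  a <- unclass(one)
  # zero out the outer shell
  ax <- (seq_len(dim(a)[1]) - (dim(a)[1] + 1) / 2) * 8
  d <- sqrt(outer(outer(ax^2, ax^2, `+`), ax^2, `+`))
  a[d > 250] <- 0
  single <- voxel_stack(a, voxel_size = 8)
  fit <- fit_two_spheres(single, threshold = 300, init_radii = c(100, 430),
                         median_prefilter = FALSE)
  expect_false(fit$chorion$converged)
  expect_true(fit$embryo$converged)
  expect_lt(abs(fit$embryo$radius - 100), 5)

  flat <- voxel_stack(array(1, c(20L, 20L, 20L)), voxel_size = 8)
  expect_error(fit_two_spheres(flat, threshold = 10), "foreground")
})

test_that("shell mask selects the analytic band and round-trips losslessly", {
  fit <- list(center = c(0, 0, 0), radius = 100, converged = TRUE)
  mask <- shell_mask(fit, band = c(-20, 20), stack_shape = c(120L, 120L, 120L),
                     voxel_size = 2)
  frac_analytic <- (4 / 3 * pi * (120^3 - 80^3)) / 240^3
  expect_lt(abs(mask_fraction(mask) / frac_analytic - 1), 0.01)
  expect_true(all(diff(mask$index_table) > 0))

  empty <- shell_mask(fit, band = c(10, 10), stack_shape = c(40L, 40L, 40L),
                      voxel_size = 2)
  expect_equal(length(empty$index_table), 0L)

  set.seed(24)
  a <- array(runif(60^3, 0, 4000), c(60L, 60L, 60L))
  vs <- voxel_stack(a, voxel_size = 4)
  mask2 <- shell_mask(fit, band = c(-30, 30), stack_shape = dim(a),
                      voxel_size = 4)
  p <- tempfile("masked")
  masked_write(vs, mask2, p)
  back <- masked_read(p)
  expect_identical(as.numeric(unclass(back)[mask2$index_table]),
                   as.numeric(a[mask2$index_table]))
  expect_true(all(unclass(back)[-mask2$index_table] == 0))

  # corrupt blob: error reports both lengths
  blob <- sprintf("%s_t%03d.blob", p, 1L)
  vals <- readBin(blob, "numeric", n = length(mask2$index_table), size = 8)
  con <- file(blob, "wb"); writeBin(vals[-1], con, size = 8); close(con)
  expect_error(masked_read(p), "blob has")

  unconv <- list(center = c(0, 0, 0), radius = 100, converged = FALSE)
  expect_error(shell_mask(unconv, c(-10, 10), c(20L, 20L, 20L), 2),
               "converge")
})

test_that("multi-timepoint masked stacks are stored and restored independently", {
  fit <- list(center = c(0, 0, 0), radius = 40, converged = TRUE)
  mask <- shell_mask(fit, band = c(-10, 10), stack_shape = c(30L, 30L, 30L),
                     voxel_size = 4)
  set.seed(25)
  stacks <- lapply(1:3, function(i)
    voxel_stack(array(runif(30^3) * i, c(30L, 30L, 30L)), voxel_size = 4))
  p <- tempfile("tl")
  masked_write(stacks, mask, p)
  for (i in 1:3) {
    back <- masked_read(p, timepoint = i, fill = -1)
    expect_equal(as.numeric(unclass(back)[mask$index_table]),
                 as.numeric(unclass(stacks[[i]])[mask$index_table]))
    expect_true(all(unclass(back)[-mask$index_table] == -1))
  }
})

test_that("channel subtraction separates germ layers on rendered stacks", {
  cfg <- small_embryo_config(seed = 5)
  sim <- simulate_embryo_tracks(cfg)
  ch <- render_channel_stacks(sim$tracks, 1, voxel_size = 4,
                              shape = c(70L, 70L, 70L))
  layers <- subtract_channels(ch$ch1, ch$ch2, ch$ch3)
  d1 <- sim$tracks$data[sim$tracks$data$frame == 1, ]
  lab <- classify_layers(layers, as.matrix(d1[, c("x_um", "y_um", "z_um")]))
  expect_gte(mean(lab == d1$layer), 0.95)

  # outputs non-negative; epiblast + mesendoderm bounded by ch3
  for (s in layers) expect_gte(min(s), 0)
  expect_true(all(unclass(layers$epiblast) + unclass(layers$mesendoderm) <=
                    unclass(ch$ch3) + 1e-6))
})

test_that("channel subtraction limiting cases and shape checks hold", {
  cfg <- small_embryo_config(seed = 6, n_cells = 30)
  sim <- simulate_embryo_tracks(cfg)
  ch <- render_channel_stacks(sim$tracks, 1, voxel_size = 4,
                              shape = c(70L, 70L, 70L))
  zero2 <- voxel_stack(array(0, dim(ch$ch2)), voxel_size = 4)
  layers <- subtract_channels(ch$ch1, zero2, ch$ch3)
  expect_equal(unclass(layers$epiblast), unclass(ch$ch3))
  expect_equal(max(layers$mesendoderm), 0)

  # ch2 exactly the nuclear-equivalent of ch3: epiblast vanishes
  layers2 <- subtract_channels(ch$ch1, ch$ch3, ch$ch3, close_radius_um = 0)
  expect_lt(max(layers2$epiblast) / max(ch$ch3), 0.01)

  small <- voxel_stack(array(0, c(10L, 10L, 10L)), voxel_size = 4)
  expect_error(subtract_channels(small, ch$ch2, ch$ch3), "shapes differ")
})

test_that("expression readout means windows and normalises globally", {
  expect_equal(eval(formals(expression_readout)$window), 3L)
  # constant stack: zero dynamic range path
  const <- voxel_stack(array(5, c(12L, 12L, 12L)), voxel_size = 2)
  expect_warning(v <- expression_readout(const, rbind(c(0, 0, 0))),
                 "dynamic range")
  expect_equal(v, 0)

  # two positions with raw means 10 and 50 normalise to 0 and 1
  a <- array(10, c(20L, 20L, 5L))
  a[13:20, , ] <- 50
  st <- voxel_stack(a, voxel_size = 1)
  pos <- gastruflow:::voxel_to_world(rbind(c(5, 10, 3), c(17, 10, 3)), st)
  v <- expression_readout(st, pos)
  expect_equal(v, c(0, 1))

  # multi-frame runs share one global normalisation
  st2 <- voxel_stack(a * 2, voxel_size = 1)
  v2 <- expression_readout(list(st, st2), list(pos, pos))
  expect_equal(v2[[1]], c(0, 40 / 90))
  expect_equal(v2[[2]], c(10 / 90, 1))
})
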