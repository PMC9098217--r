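test_that("noise-free datasets sample the exact simulated contour", {
  p <- prw_params(dtarg = 1e5)
  ds <- generate_dataset(p, n = 12, imaging_interval = 5, seed = 1)
  tr <- ds$trajectories
  # consecutive sampled points are v * interval apart in arc length; with
  # frozen shape and 5-min frames every step chord is at most that long
  seg <- tr |>
    dplyr::group_by(airineme_id) |>
    dplyr::summarise(max_chord = max(sqrt(diff(x_um)^2 + diff(y_um)^2)))
  expect_true(all(seg$max_chord <= p$v * 5 + 1e-9))
  expect_true("heading_rad" %in% names(tr))
  # contour length never exceeds lmax
  len <- tr |>
    dplyr::group_by(airineme_id) |>
    dplyr::summarise(l = sum(sqrt(diff(x_um)^2 + diff(y_um)^2)))
  expect_true(all(len$l <= p$lmax + p$v * p$dt))
  # reproducibility
  ds2 <- generate_dataset(p, n = 12, imaging_interval = 5, seed = 1)
  expect_identical(ds$trajectories, ds2$trajectories)
  expect_error(generate_dataset(p, noise_sd = -1), "noise_sd")
})

test_that("position noise perturbs samples by the stated amount", {
  p <- prw_params(dtarg = 1e5)
  clean <- generate_dataset(p, n = 40, imaging_interval = 5, seed = 2)
  noisy <- generate_dataset(p, n = 40, imaging_interval = 5, noise_sd = 0.5,
                            seed = 2)
  expect_false("heading_rad" %in% names(noisy$trajectories))
  dx <- noisy$trajectories$x_um - clean$trajectories$x_um
  dy <- noisy$trajectories$y_um - clean$trajectories$y_um
  expect_equal(sd(c(dx, dy)), 0.5, tolerance = 0.05)
  expect_lt(abs(mean(c(dx, dy))), 0.02)
})

test_that("dataset scale emulates the digitized-airineme bookkeeping", {
  p <- prw_params(dtarg = 1e5)
  # dense contour digitization: ~80 points per full-length airineme
  ds <- generate_dataset(p, n = 70, imaging_interval = 0.7, seed = 3)
  pts <- nrow(ds$trajectories)
  expect_gt(pts / 70, 60); expect_lt(pts / 70, 100)
  # frame sampling at 5 min: ~12 frames per 56-min airineme
  ds5 <- generate_dataset(p, n = 10, imaging_interval = 5, seed = 3)
  expect_equal(max(ds5$trajectories$frame), 12, tolerance = 1)
})

test_that("the MLE recovers the generator's curvature from datasets", {
  p <- prw_params(dtheta = 0.1838, dtarg = 1e5)
  ds <- generate_dataset(p, n = 70, imaging_interval = 0.7, seed = 4)
  fit <- mle_dtheta(tangent_autocorrelation(ds$trajectories, v = p$v, max_pairs_per_path = 0), v = p$v)
  expect_true(fit$ci90[1] <= p$dtheta && p$dtheta <= fit$ci90[2])
})

test_that("parameter recovery holds across curvatures with calibrated bias", {
  # 100 replicate experiments at each of three curvatures; the 90% CI must
  # cover truth in >= 85 and the pooled bias must stay within 7%
  p_base <- prw_params(dtarg = 1e5)
  for (dth in c(0.05, 0.1838, 0.5)) {
    p <- prw_params(dtheta = dth, dtarg = 1e5)
    cover <- 0; est <- numeric(100)
    for (r in 1:100) {
      ds <- generate_dataset(p, n = 70, imaging_interval = 0.7,
                             seed = 5000 + 101 * r)
      fit <- mle_dtheta(tangent_autocorrelation(ds$trajectories, v = p$v, max_pairs_per_path = 0), v = p$v)
      est[r] <- fit$dtheta_hat
      if (fit$ci90[1] <= dth && dth <= fit$ci90[2]) cover <- cover + 1
    }
    expect_gte(cover, 85)
    expect_lt(abs(mean(est) - dth) / dth, 0.07)
  }
})

test_that("rendered images have the right line profile, noise and linearity", {
  tr <- straight_path(n_frames = 11, v = 4, dt = 5, angle = 0, x0 = 0, y0 = 0)
  st <- render_images(tr, pixel_size = 0.5, psf_sigma = 1, snr = Inf)
  img <- st$images[[1]]
  # transverse profile through the ridge middle is Gaussian with sd psf_sigma
  mid_col <- round(ncol(img) / 2)
  prof <- img[, mid_col]
  ys <- st$origins[[1]][2] + (seq_len(nrow(img)) - 1) * 0.5
  fit_sd <- sqrt(sum(prof * (ys - sum(prof * ys) / sum(prof))^2) / sum(prof))
  expect_lt(abs(fit_sd - 1) / 1, 0.05)
  # noise off: constant background far from the line
  corner <- img[1:3, 1:3]
  expect_lt(max(abs(corner)), 1e-6)
  # linearity: doubling flux doubles every pixel
  st2 <- render_images(tr, pixel_size = 0.5, psf_sigma = 1, snr = Inf,
                       flux = 2)
  expect_equal(st2$images[[1]], 2 * img, tolerance = 1e-12)
  # calibrated noise: peak / noise-sd = snr within 5%
  stn <- render_images(tr, pixel_size = 0.5, psf_sigma = 1, snr = 5, seed = 2)
  resid <- stn$images[[1]] - img
  expect_equal(max(img) / sd(resid), 5, tolerance = 0.05)
})

test_that("synthetic three-point angles match the simulator at zero jitter", {
  ds <- generate_dataset(prw_params(), n = 300, imaging_interval = 5,
                         seed = 6)
  ang <- measure_contact_angles_synthetic(ds, center_jitter_sd = 0)
  truth <- ds$contacts$contact_angle_rad[ds$contacts$contacted] * 180 / pi
  expect_equal(ang$angle_deg, truth, tolerance = 1e-9)
  # jitter inflates the angle spread monotonically
  a1 <- measure_contact_angles_synthetic(ds, center_jitter_sd = 2, seed = 7)
  a2 <- measure_contact_angles_synthetic(ds, center_jitter_sd = 60, seed = 7)
  expect_gt(sd(a2$angle_deg - ang$angle_deg), sd(a1$angle_deg - ang$angle_deg))
  # no contacts: empty with warning
  ds0 <- generate_dataset(prw_params(dtarg = 300), n = 5, seed = 8)
  expect_warning(out <- measure_contact_angles_synthetic(ds0), "no contacts")
  expect_equal(nrow(out), 0)
})
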