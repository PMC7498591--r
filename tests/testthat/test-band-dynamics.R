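test_that("axial profiles account for photons and add over rows", {
  # uniform image at the background level: all-zero profile
  prof0 <- axial_profile(matrix(100, 32, 48), roi_rows = 0:31,
                         background_level = 100)
  expect_true(all(prof0$intensity == 0))
  expect_equal(prof0$position_um, (0:47) * PX_UM)
  expect_error(axial_profile(matrix(100, 32, 48), roi_rows = integer()),
               "empty")

  # single spot: profile integral equals the spot energy within 2%
  img <- render_spots(48, 48, 24, 20, n_dyes = 4L)
  prof <- axial_profile(img, 0:47, background_level = 100)
  expect_lt(abs(sum(prof$intensity) - 4 * 300) / (4 * 300), 0.02)

  # two identical spots in the same columns, different rows: profile doubles
  img2 <- render_spots(48, 48, c(14, 34), c(20, 20), n_dyes = 4L)
  prof2 <- axial_profile(img2, 0:47, background_level = 100)
  expect_equal(sum(prof2$intensity), 2 * sum(prof$intensity), tolerance = 0.01)
})

test_that("gaussian band fits recover noise-free and noisy parameters", {
  x <- seq(0, 200, by = 1)
  y <- 10 + 80 * exp(-(x - 100)^2 / (2 * 15^2))
  fit <- fit_gaussian_band(tibble::tibble(position_um = x, intensity = y))
  expect_true(fit$valid)
  expect_equal(fit$mean_um, 100, tolerance = 1e-6)
  expect_equal(fit$sigma_um, 15, tolerance = 1e-6)
  expect_equal(band_hwhm(fit$sigma_um), 15 * sqrt(2 * log(2)), tolerance = 1e-6)

  # SNR 10: mean within half a pixel, sigma within 10%
  set.seed(51)
  noisy <- y + rnorm(length(y), 0, 8)
  fitn <- fit_gaussian_band(tibble::tibble(position_um = x, intensity = noisy))
  expect_true(fitn$valid)
  expect_lt(abs(fitn$mean_um - 100), 0.5 * PX_UM * 10)
  expect_lt(abs(fitn$sigma_um - 15) / 15, 0.10)

  # degenerate inputs are invalid fits, not errors
  expect_false(fit_gaussian_band(tibble::tibble(position_um = x,
                                                intensity = rep(0, length(x))))$valid)
  expect_false(fit_gaussian_band(tibble::tibble(position_um = x,
                                                intensity = rep(5, length(x))))$valid)
})

test_that("a static band keeps a constant fitted width", {
  cam <- test_camera(32, 128, em_gain = 1, read_noise_sd = 3, baseline = 100,
                     photons_per_dye = 200)
  set.seed(52)
  traj <- dplyr::bind_rows(lapply(0:9, function(f) {
    tibble::tibble(frame = f,
                   axial_um = rep(60 * PX_UM, 40) , # fixed band centre
                   transverse_um = runif(40, 2, 6),
                   n_dyes = 2L)
  }))
  traj$axial_um <- traj$axial_um + rep(rnorm(40, 0, 4 * PX_UM), 10)
  st <- render_video(traj, cam, seed = 53)
  trace <- stacking_trace(st, roi_rows = 0:31)
  sig <- trace$fits$sigma_um[trace$fits$valid]
  expect_gt(length(sig), 8)
  expect_lt(stats::sd(sig) / mean(sig), 0.15)
})

test_that("pure diffusion broadens the band as sigma^2 ~ 2 D t", {
  d_gel <- 2 # um^2/s
  ch <- channel_model(gel_start_um = -1000, gel_end_um = 1e6,
                      v_open_umps = 1e-9, d_gel_um2ps = d_gel,
                      d_open_um2ps = d_gel, width_um = 8,
                      calib_A_kda = 200, calib_k = 2e12) # ~zero drift in gel
  cam <- test_camera(32, 256, em_gain = 1, read_noise_sd = 0, baseline = 0,
                     photons_per_dye = 100)
  set.seed(54)
  sim <- simulate_trajectories(species_spec("X", 30, 2, 400), labeling_model(1),
                               ch, cam, duration_s = 8, plug_length_um = 1,
                               seed = 55)
  # recentre the plug mid-field
  sim$trajectories$axial_um <- sim$trajectories$axial_um + 1034.15
  sim$trajectories$in_fov <- TRUE
  st <- render_video(sim, seed = 56, noise = FALSE)
  trace <- stacking_trace(st, roi_rows = 0:31)
  fits <- trace$fits[trace$fits$valid, ]
  expect_gt(nrow(fits), 100)
  slope <- coef(lm(I(sigma_um^2) ~ time_s, data = fits))[2L]
  expect_gt(slope, 0.7 * 2 * d_gel)
  expect_lt(slope, 1.5 * 2 * d_gel)
  # width does not shrink overall
  expect_gt(mean(utils::tail(fits$sigma_um, 20)),
            mean(utils::head(fits$sigma_um, 20)))
})

test_that("stacking runs show width minimum near full plug entry", {
  # scaled stacking run: 40 um plug at ratio 20
  v_gel <- 5
  m <- exp(log(200) - v_gel * 1e-6 / 12e3 * 5e8)
  ch <- channel_model(gel_start_um = 45, gel_end_um = 5000, v_open_umps = 100,
                      d_gel_um2ps = 0.05, d_open_um2ps = 0.05,
                      calib_A_kda = 200, calib_k = 5e8, width_um = 8)
  cam <- test_camera(32, 360, em_gain = 1, read_noise_sd = 5, baseline = 100,
                     photons_per_dye = 150)
  sim <- simulate_trajectories(species_spec("X", m - 3 * 0.6289, 3, 250),
                               labeling_model(1), ch, cam, duration_s = 1.2,
                               plug_length_um = 40, seed = 57)
  st <- render_video(sim, seed = 58)
  trace <- stacking_trace(st, roi_rows = 0:31)
  # fitted mean position advances monotonically (within fit noise)
  fits <- trace$fits[trace$fits$valid, ]
  expect_gt(cor(fits$time_s, fits$mean_um, method = "spearman"), 0.95)
  # width minimum falls inside the plug-entry window (full entry ~0.4 s;
  # the fit can lock onto the stacked spike slightly before the tail is in)
  expect_gt(trace$stacking_time_s, 0.05)
  expect_lt(trace$stacking_time_s, 0.6)
  # end-to-end compression 40/20 = 2 um: fitted sigma far below the plug
  # scale, and the band broadens again after the minimum
  expect_lt(trace$min_width_um, 2)
  expect_gt(mean(utils::tail(fits$sigma_um, 5)), trace$min_width_um)
})
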