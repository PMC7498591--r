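test_that("labeling draws follow the binomial dye model", {
  sp <- species_spec("BSA", 66.4, 59, 2000)
  lab <- sample_labeling(sp, labeling_model(0.5, 0.6289), seed = 3)
  expect_equal(nrow(lab), 2000)
  # population mean effective mass ~ 66.4 + 29.5 * 0.6289 = 84.95 kDa
  se <- 0.6289 * sqrt(59 * 0.25) / sqrt(2000)
  expect_lt(abs(mean(lab$mass_kda) - 84.95255), 4 * se)

  # zero efficiency: every molecule dark, nothing renderable
  dark <- sample_labeling(sp, labeling_model(0), seed = 3)
  expect_true(all(dark$dark))
  expect_equal(dark$mass_kda, rep(66.4, 2000))

  # full efficiency: deterministic dye count and mass
  full <- sample_labeling(species_spec("X", 10, 10, 50), labeling_model(1),
                          seed = 3)
  expect_true(all(full$n_dyes == 10L))
  expect_equal(full$mass_kda, rep(10 + 6.289, 50))
})

test_that("noise-free ballistic motion is linear in frame index", {
  cam <- test_camera(32, 64)
  ch <- channel_model(gel_start_um = 0.5, gel_end_um = 1e6, v_open_umps = 40,
                      d_gel_um2ps = 0, d_open_um2ps = 0, width_um = 8,
                      calib_A_kda = 200, calib_k = 5e8)
  m <- 30 + 0.6289 # effective mass at full labeling of one site
  v_gel <- (log(200) - log(m)) / 5e8 * 12e3 * 1e6
  sim <- simulate_trajectories(species_spec("X", 30, 1, 1), labeling_model(1),
                               ch, cam, duration_s = 2, plug_length_um = 0.5,
                               seed = 4)
  x <- sim$trajectories$axial_um
  # after gel entry the drift is exactly v_gel per frame interval
  steps <- diff(x[x > 0.5])
  expect_gt(length(steps), 20)
  expect_equal(steps, rep(v_gel / FPS, length(steps)), tolerance = 1e-10)
})

test_that("a 200 um plug compresses to ~8 um at 25x velocity ratio", {
  # v_open / v_gel = 25 with v_gel = 4 um/s; continuity predicts
  # 200 / 25 = 8 um end-to-end just after full entry
  m <- exp(log(200) - 4e-6 / 12e3 * 5e8)
  ch <- channel_model(gel_start_um = 210, gel_end_um = 5000,
                      v_open_umps = 100, d_gel_um2ps = 0.01,
                      d_open_um2ps = 0.01, calib_A_kda = 200, calib_k = 5e8)
  sim <- simulate_trajectories(species_spec("X", m - 6.289, 10, 300),
                               labeling_model(1), ch, test_camera(),
                               duration_s = 3, plug_length_um = 200, seed = 7)
  tr <- sim$trajectories
  all_in <- vapply(split(tr$axial_um >= 210, tr$frame), all, logical(1))
  f_entry <- as.integer(names(which(all_in)))[1L]
  extent <- diff(range(tr$axial_um[tr$frame == f_entry]))
  expect_lt(abs(extent - 8) / 8, 0.15)
})

test_that("in-gel velocity decreases strictly with effective mass", {
  ch <- channel_model(gel_start_um = 0, gel_end_um = 1e5, v_open_umps = 100,
                      d_gel_um2ps = 0, d_open_um2ps = 0,
                      calib_A_kda = 200, calib_k = 2.8e9)
  sp <- dplyr::bind_rows(
    species_spec("light", 20 - 0.6289, 1, 5),
    species_spec("heavy", 80 - 0.6289, 1, 5)
  )
  sim <- simulate_trajectories(sp, labeling_model(1), ch, test_camera(),
                               duration_s = 2, plug_length_um = 1, seed = 5)
  v <- sim$trajectories |>
    dplyr::group_by(.data$species) |>
    dplyr::summarise(v = (max(.data$axial_um) - min(.data$axial_um)) /
                       (max(.data$time_s) - min(.data$time_s)))
  expect_gt(v$v[v$species == "light"], v$v[v$species == "heavy"])
})

test_that("masses at or above the calibration ceiling are rejected", {
  ch <- channel_model(gel_start_um = 0, gel_end_um = 100, calib_A_kda = 100)
  expect_error(
    simulate_trajectories(species_spec("huge", 150, 1, 2), labeling_model(1),
                          ch, test_camera(), duration_s = 1, seed = 1),
    "ceiling"
  )
})

test_that("rendering conserves photons and respects the baseline", {
  cam <- test_camera(48, 48, em_gain = 1, read_noise_sd = 0, baseline = 100,
                     photons_per_dye = 250)
  # empty field, noise off: every pixel at baseline
  empty <- render_video(tibble::tibble(frame = integer(), axial_um = numeric(),
                                       transverse_um = numeric(),
                                       n_dyes = integer()),
                        cam, noise = FALSE, n_frames = 2L)
  expect_true(all(empty$frames[[1L]] == 100L))

  # one molecule, noise off, gain 1: summed counts above baseline equal
  # n_dyes * photons_per_dye up to PSF truncation and rounding
  traj <- tibble::tibble(frame = 0L, axial_um = 24 * PX_UM,
                         transverse_um = 24 * PX_UM, n_dyes = 4L)
  img <- render_video(traj, cam, noise = FALSE)$frames[[1L]]
  total <- sum(img - 100L)
  # integer rounding of faint tail pixels loses a few counts
  expect_lt(abs(total - 4 * 250) / (4 * 250), 0.01)

  # Monte Carlo mean matches the noise-free expectation
  camn <- test_camera(24, 24, em_gain = 1, read_noise_sd = 3, baseline = 100,
                      photons_per_dye = 250)
  traj2 <- tibble::tibble(frame = 0:399, axial_um = 12 * PX_UM,
                          transverse_um = 12 * PX_UM, n_dyes = 2L)
  noisy <- render_video(traj2, camn, seed = 9)
  mean_img <- Reduce(`+`, lapply(noisy$frames, as.numeric)) / 400
  expected <- as.numeric(render_video(traj2[1, ], camn, noise = FALSE)$frames[[1L]])
  # per-pixel sd <= sqrt(peak photons + read^2); 3 standard errors
  peak <- max(expected) - 100
  tol <- 3 * sqrt(peak + 9) / sqrt(400)
  expect_lt(max(abs(matrix(mean_img, 24) - expected)), tol + 0.5)
})

test_that("datasets round-trip bit-identically and deterministically", {
  ch <- channel_model(gel_start_um = 5, gel_end_um = 1000, v_open_umps = 100,
                      calib_k = 2.8e9, width_um = 8)
  cam <- camera_model(frame_shape = c(32L, 120L))
  sim <- simulate_trajectories(species_spec("X", 30, 5, 6), labeling_model(1),
                               ch, cam, duration_s = 1,
                               plug_length_um = 5, seed = 6)
  st <- render_video(sim, seed = 8)
  d1 <- file.path(tempdir(), "ds1")
  d2 <- file.path(tempdir(), "ds2")
  p1 <- write_dataset(st, sim$truth, d1, config = list(seed = 6))
  back <- read_dataset(d1)
  expect_identical(back$stack$frames, st$frames)
  expect_equal(nrow(back$truth), nrow(sim$truth))

  # same seed + config twice: identical TIFF bytes
  sim2 <- simulate_trajectories(species_spec("X", 30, 5, 6), labeling_model(1),
                                ch, cam, duration_s = 1,
                                plug_length_um = 5, seed = 6)
  st2 <- render_video(sim2, seed = 8)
  p2 <- write_dataset(st2, sim2$truth, d2, config = list(seed = 6))
  expect_identical(readBin(p1[["stack"]], "raw", file.size(p1[["stack"]])),
                   readBin(p2[["stack"]], "raw", file.size(p2[["stack"]])))

  # truth accounting: one CSV row per visible molecule-frame
  expect_equal(nrow(back$truth), sum(sim$trajectories$in_fov))
})
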