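test_that("arrival histograms bin kymograph detections correctly", {
  empty <- arrival_histogram(tibble::tibble(col = numeric()), FPS)
  expect_true(all(empty$bins$count == 0))

  # sampled band: histogram Gaussian fit recovers the generating moments
  set.seed(61)
  n <- 2000
  times <- rnorm(n, 74.5, 5.44)
  p <- tibble::tibble(col = times * FPS)
  ep <- arrival_histogram(p, FPS, bin_width_s = 1)
  centres <- (ep$bins$bin_start_s + ep$bins$bin_end_s) / 2
  fit <- fit_gaussian_band(tibble::tibble(position_um = centres,
                                          intensity = ep$bins$count))
  expect_true(fit$valid)
  expect_lt(abs(fit$mean_um - 74.5), 2 * 5.44 / sqrt(n))
  expect_lt(abs(fit$sigma_um - 5.44) / 5.44, 2 * 1 / sqrt(2 * n) + 0.02)

  # referencing to the first particle puts it in bin 0
  ep2 <- arrival_histogram(p, FPS, bin_width_s = 5, t_reference = min(times))
  expect_gte(ep2$bins$count[1L], 1L)
  expect_equal(ep2$underflow, 0L)
  # pre-reference particles go to the underflow, not a bin
  ep3 <- arrival_histogram(p, FPS, bin_width_s = 5, t_reference = 80)
  expect_equal(ep3$underflow + sum(ep3$bins$count), n)
  expect_gt(ep3$underflow, 0L)
})

test_that("stripe counting is digital and documents re-entries", {
  none <- count_frame_stack(tibble::tibble(frame = integer(), row = numeric(),
                                           col = numeric()),
                            3, stripe_col = 10)
  expect_equal(none$unique_count, 0L)

  # one molecule crossing twice (reflected trajectory) counts twice
  p <- tibble::tibble(frame = c(0L, 5L), row = c(4, 4), col = c(11, 11.5))
  twice <- count_frame_stack(p, 3, stripe_col = 10)
  expect_equal(twice$unique_count, 2L)

  # a lingering molecule is only counted on first entry
  ling <- tibble::tibble(frame = 0:2, row = rep(4, 3), col = c(11, 11.1, 11.05))
  once <- count_frame_stack(ling, 3, stripe_col = 10)
  expect_equal(once$unique_count, 1L)

  expect_error(count_frame_stack(p, 3, stripe_col = 62, frame_width = 64),
               "outside")
})

test_that("stripe counts match simulator ground truth within 5%", {
  v <- 3 * PX_UM * FPS # exactly 3 px/frame
  k <- (log(200) - log(85)) * 12e3 / (v * 1e-6)
  ch <- channel_model(gel_start_um = 2, gel_end_um = 1e5, v_open_umps = 50,
                      calib_A_kda = 200, calib_k = k,
                      d_gel_um2ps = 0.05, d_open_um2ps = 0.05, width_um = 24)
  cam <- camera_model(frame_shape = c(96L, 480L))
  n_mol <- 200L
  sim <- simulate_trajectories(species_spec("X", 85 - 30 * 0.6289, 30, n_mol),
                               labeling_model(1), ch, cam, duration_s = 12,
                               plug_length_um = 60, seed = 63)
  parts <- truth_particles(sim)
  res <- count_frame_stack(parts, 3, stripe_col = 300, frame_rate = FPS)
  expect_lt(abs(res$unique_count - n_mol) / n_mol, 0.05)
  # stripe-position invariance in the uniform-flow region
  res2 <- count_frame_stack(parts, 3, stripe_col = 250, frame_rate = FPS)
  expect_lt(abs(res2$unique_count - res$unique_count) / res$unique_count, 0.05)
})

test_that("peak finding locates, merges and counts correctly", {
  mk_ep <- function(counts, bw = 5) {
    p <- tibble::tibble(col = rep((seq_along(counts) - 0.5) * bw,
                                  counts) * 1)
    arrival_histogram(p, 1, bin_width_s = bw)
  }
  # triangular histogram: one peak at the apex
  tri <- mk_ep(c(1, 3, 6, 3, 1))
  pk <- find_peaks(tri, min_separation_s = 10, min_height = 1)
  expect_equal(nrow(pk), 1L)
  expect_equal(pk$time_s, 12.5)
  expect_equal(pk$n_particles, 14L)

  # peaks 2 bins apart with min_separation 10 s merge, keeping the taller
  close2 <- mk_ep(c(1, 8, 2, 6, 1), bw = 1)
  merged <- find_peaks(close2, min_separation_s = 10, min_height = 1)
  expect_equal(nrow(merged), 1L)
  expect_equal(merged$time_s, 1.5)

  # well-separated species produce one peak each with full digital counts
  set.seed(65)
  means <- c(55, 69, 82, 114)
  times <- as.vector(vapply(means, function(m) rnorm(200, m, 3), numeric(200)))
  ep <- arrival_histogram(tibble::tibble(col = times * FPS), FPS,
                          bin_width_s = 5)
  peaks <- find_peaks(ep, min_separation_s = 10, min_height = 5)
  expect_equal(nrow(peaks), 4L)
  expect_true(all(abs(peaks$time_s - means) <= 5))
  expect_equal(sum(peaks$n_particles), sum(ep$bins$count))
  expect_true(all(peaks$n_particles >= peaks$height))
})

test_that("per-frame normalized intensity histograms separate light and heavy", {
  # early light species (2 dyes) and late heavy species (4 dyes), with a
  # constant bright reference in every frame to normalize against
  frames <- 0:99
  p <- dplyr::bind_rows(
    tibble::tibble(frame = frames, energy = 1000),            # reference
    tibble::tibble(frame = rep(0:49, 2), energy = 200),       # early light
    tibble::tibble(frame = rep(50:99, 2), energy = 420)       # late heavy
  )
  w <- tibble::tibble(start_s = c(0, 50) / FPS, end_s = c(50, 100) / FPS)
  ih <- intensity_histograms(p, w, frame_rate = FPS, n_bins = 10)
  expect_false(any(ih$windows$empty))
  mean_norm <- function(id) {
    h <- ih$histograms[ih$histograms$window_id == id, ]
    sum((h$bin_left + h$bin_right) / 2 * h$count) / sum(h$count)
  }
  expect_gt(mean_norm(2L), mean_norm(1L))

  # single particle per frame: everything normalizes to 1
  solo <- intensity_histograms(tibble::tibble(frame = 0:9, energy = 5 + (0:9)),
                               tibble::tibble(start_s = 0, end_s = 1),
                               frame_rate = FPS, n_bins = 5)
  h <- solo$histograms
  expect_equal(sum(h$count[h$bin_right == 1]), 10L)

  # empty window flagged, not an error
  ihe <- intensity_histograms(p, tibble::tibble(start_s = 1000, end_s = 1001),
                              frame_rate = FPS)
  expect_true(ihe$windows$empty[1L])
  expect_error(
    intensity_histograms(p, tibble::tibble(start_s = c(0, 1), end_s = c(2, 3)),
                         FPS),
    "disjoint"
  )
})
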