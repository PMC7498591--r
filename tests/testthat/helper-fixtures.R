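# Shared fixture builders. Everything is generated in code; pixel size
# 267 nm and frame rate 19.31 Hz throughout unless a test says otherwise.

PX_UM <- 0.267
FPS <- 19.31

# Camera for small, quiet test frames.
test_camera <- function(rows = 64L, cols = 64L, ...) {
  camera_model(frame_shape = c(rows, cols), ...)
}

# A single rendered frame containing spots at given 0-based (row, col)
# pixel positions; noise off by default for exact checks.
render_spots <- function(rows, cols, row_px, col_px, n_dyes = 5L,
                         camera = NULL, noise = FALSE, seed = 1) {
  camera <- camera %||% test_camera(rows, cols, em_gain = 1,
                                    read_noise_sd = 2, baseline = 100,
                                    photons_per_dye = 300)
  traj <- tibble::tibble(
    frame = 0L,
    axial_um = col_px * PX_UM + camera$fov_origin_um,
    transverse_um = row_px * PX_UM,
    n_dyes = as.integer(n_dyes)
  )
  render_video(traj, camera, seed = seed, noise = noise)$frames[[1L]]
}

# Greedy matching of detections to ground truth within `radius` px;
# returns recall, precision and localization RMSE.
match_detections <- function(det, truth_row_px, truth_col_px, truth_frame,
                             radius = 2) {
  tp <- 0L
  err2 <- numeric()
  n_truth <- length(truth_row_px)
  for (f in unique(truth_frame)) {
    ti <- which(truth_frame == f)
    dd <- det[det$frame == f, , drop = FALSE]
    used <- rep(FALSE, nrow(dd))
    for (i in ti) {
      if (!nrow(dd)) next
      d2 <- (dd$row - truth_row_px[i])^2 + (dd$col - truth_col_px[i])^2
      d2[used] <- Inf
      j <- which.min(d2)
      if (length(j) && is.finite(d2[j]) && d2[j] <= radius^2) {
        tp <- tp + 1L
        used[j] <- TRUE
        err2 <- c(err2, d2[j])
      }
    }
  }
  list(recall = tp / n_truth, precision = tp / max(nrow(det), 1L),
       rmse = sqrt(mean(err2)))
}

# Four-species ladder (effective masses 17/31/46/85 kDa at full labeling)
# migrating through a short scaled-down gel; used by the end-to-end
# calibration tests. Returns the simulation plus its generative truth.
ladder_simulation <- function(seed = 11, copies = 40L) {
  dm <- 0.6289
  cam <- camera_model(frame_shape = c(96L, 480L))
  ch <- channel_model(
    gel_start_um = 5, gel_end_um = 1000, field_vpm = 12e3,
    calib_A_kda = 200, calib_k = 2.8e9,
    v_open_umps = 200, d_gel_um2ps = 0.5, d_open_um2ps = 5, width_um = 24
  )
  sp <- dplyr::bind_rows(
    species_spec("LYS", 17 - 5 * dm, 5, copies),
    species_spec("CA", 31 - 10 * dm, 10, copies),
    species_spec("OA", 46 - 15 * dm, 15, copies),
    species_spec("BSA", 85 - 30 * dm, 30, copies)
  )
  sim <- simulate_trajectories(sp, labeling_model(1), ch, cam,
                               duration_s = 36, plug_length_um = 10,
                               seed = seed)
  list(sim = sim, camera = cam, channel = ch,
       masses_kda = c(17, 31, 46, 85))
}

# Convert simulator ground truth to a detection-like particle table
# (row/col in 0-based px), bypassing the imaging chain.
truth_particles <- function(sim, camera = NULL) {
  camera <- camera %||% sim$camera
  tr <- sim$truth
  tibble::tibble(
    frame = tr$frame,
    row = tr$transverse_um / (camera$pixel_size_nm / 1000),
    col = (tr$axial_um - camera$fov_origin_um) / (camera$pixel_size_nm / 1000),
    energy = as.numeric(tr$n_dyes),
    area = 1L
  )
}
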