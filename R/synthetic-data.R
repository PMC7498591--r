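#' Specify a protein species for simulation
#'
#' @param name Species label.
#' @param bare_mass_kda Unlabeled molecular weight in kDa (> 0).
#' @param n_label_sites Number of labelable residues (lysines or cysteines).
#' @param copy_number Number of molecules to simulate.
#' @return A one-row tibble; rows from several calls can be combined with
#'   [dplyr::bind_rows()] to form a species table.
#' @examples
#' dplyr::bind_rows(
#'   species_spec("CA", 29.0, 18, 200),
#'   species_spec("BSA", 66.4, 59, 200)
#' )
#' @export
species_spec <- function(name, bare_mass_kda, n_label_sites, copy_number) {
  check_scalar(bare_mass_kda, "bare_mass_kda", positive = TRUE)
  check_scalar(n_label_sites, "n_label_sites", nonneg = TRUE)
  check_scalar(copy_number, "copy_number", nonneg = TRUE)
  tibble(
    name = as.character(name),
    bare_mass_kda = bare_mass_kda,
    n_label_sites = as.integer(n_label_sites),
    copy_number = as.integer(copy_number)
  )
}

#' Dye-labeling model
#'
#' Each reactive residue is conjugated independently with probability
#' `efficiency`; every conjugated dye adds `delta_m_kda` to the molecular
#' weight (0.6289 kDa for Atto647N NHS-ester).
#'
#' @param efficiency Labeling efficiency, fraction in `[0, 1]`.
#' @param delta_m_kda Mass increment per dye in kDa.
#' @export
labeling_model <- function(efficiency = 0.5, delta_m_kda = 0.6289) {
  check_fraction(efficiency, "efficiency")
  check_scalar(delta_m_kda, "delta_m_kda", nonneg = TRUE)
  structure(list(efficiency = efficiency, delta_m_kda = delta_m_kda),
            class = "labeling_model")
}

#' Channel and transport model
#'
#' Describes the separation channel geometry and the piecewise transport law
#' used by [simulate_trajectories()]: constant plug velocity `v_open_umps`
#' before the gel interface, mass-dependent electrophoretic drift
#' `mu(m) * field` inside the gel with `mu(m) = (ln A - ln m) / k`, and the
#' same drift multiplied by `post_gel_speedup` after the gel exit (proteins
#' accelerate roughly 70-fold in the low-resistance open channel).
#'
#' @param gel_start_um,gel_end_um Axial coordinates of the gel interface and
#'   gel exit in um (`gel_start_um < gel_end_um`).
#' @param field_vpm Electric field strength in V/m (default 12,000, i.e.
#'   60 V/cm).
#' @param calib_A_kda,calib_k Generative mobility calibration
#'   `MW = A exp(-k mu)`: pre-exponential in kDa and decay constant in
#'   (m^2/(V s))^-1.
#' @param v_open_umps Plug velocity before the gel in um/s (a ~200 um plug
#'   traverses its own length in about 2 s at the default 100 um/s).
#' @param post_gel_speedup Dimensionless velocity multiplier on gel exit
#'   (default 70).
#' @param d_gel_um2ps,d_open_um2ps Diffusivities in and outside the gel,
#'   um^2/s.
#' @param width_um Transverse channel width in um (reflecting walls).
#' @export
channel_model <- function(gel_start_um, gel_end_um,
                          field_vpm = 12e3,
                          calib_A_kda = 200, calib_k = 5e8,
                          v_open_umps = 100,
                          post_gel_speedup = 70,
                          d_gel_um2ps = 0.2, d_open_um2ps = 20,
                          width_um = 50) {
  check_scalar(gel_start_um, "gel_start_um")
  check_scalar(gel_end_um, "gel_end_um")
  if (gel_start_um >= gel_end_um) abort("`gel_start_um` must be < `gel_end_um`.")
  check_scalar(field_vpm, "field_vpm", positive = TRUE)
  check_scalar(calib_A_kda, "calib_A_kda", positive = TRUE)
  check_scalar(calib_k, "calib_k", positive = TRUE)
  check_scalar(v_open_umps, "v_open_umps", positive = TRUE)
  if (post_gel_speedup < 1) abort("`post_gel_speedup` must be >= 1.")
  check_scalar(d_gel_um2ps, "d_gel_um2ps", nonneg = TRUE)
  check_scalar(d_open_um2ps, "d_open_um2ps", nonneg = TRUE)
  check_scalar(width_um, "width_um", positive = TRUE)
  structure(
    list(
      gel_start_um = gel_start_um, gel_end_um = gel_end_um,
      field_vpm = field_vpm,
      calib_A_kda = calib_A_kda, calib_k = calib_k,
      v_open_umps = v_open_umps, post_gel_speedup = post_gel_speedup,
      d_gel_um2ps = d_gel_um2ps, d_open_um2ps = d_open_um2ps,
      width_um = width_um
    ),
    class = "channel_model"
  )
}

#' EMCCD camera model
#'
#' Defaults reproduce the acquisition regime of the device: 267 nm pixels,
#' 19.31 frames/s, 512 x 512 frames, a diffraction-limited PSF of sigma
#' 1.1 px (~294 nm at NA 1.45 / 670 nm emission). EM-gain excess noise is
#' folded into `read_noise_sd` rather than modelled as a gamma cascade.
#'
#' @param pixel_size_nm Pixel size in nm.
#' @param frame_rate Frame rate in Hz.
#' @param frame_shape Integer `(rows, cols)` of each frame.
#' @param psf_sigma_px PSF standard deviation in pixels.
#' @param photons_per_dye Expected photons per dye per frame.
#' @param em_gain Camera counts per detected photon.
#' @param read_noise_sd Gaussian read noise sd in counts.
#' @param baseline Camera offset in counts.
#' @param bit_depth Bits per pixel (values clipped to `[0, 2^bit_depth - 1]`).
#' @param fov_origin_um Axial position (um) imaged by column 0; lets the
#'   field of view be placed part-way along a channel much longer than the
#'   ~137 um covered by 512 columns, as in imaging 1.3-2.3 mm into the gel.
#' @export
camera_model <- function(pixel_size_nm = 267, frame_rate = 19.31,
                         frame_shape = c(512L, 512L),
                         psf_sigma_px = 1.1,
                         photons_per_dye = 200, em_gain = 5,
                         read_noise_sd = 20, baseline = 100,
                         bit_depth = 16, fov_origin_um = 0) {
  check_scalar(pixel_size_nm, "pixel_size_nm", positive = TRUE)
  check_scalar(frame_rate, "frame_rate", positive = TRUE)
  if (length(frame_shape) != 2L || any(frame_shape < 1)) {
    abort("`frame_shape` must be two positive integers (rows, cols).")
  }
  check_scalar(psf_sigma_px, "psf_sigma_px", positive = TRUE)
  check_scalar(photons_per_dye, "photons_per_dye", nonneg = TRUE)
  check_scalar(em_gain, "em_gain", positive = TRUE)
  check_scalar(read_noise_sd, "read_noise_sd", nonneg = TRUE)
  check_scalar(baseline, "baseline", nonneg = TRUE)
  structure(
    list(
      pixel_size_nm = pixel_size_nm, frame_rate = frame_rate,
      frame_shape = as.integer(frame_shape),
      psf_sigma_px = psf_sigma_px,
      photons_per_dye = photons_per_dye, em_gain = em_gain,
      read_noise_sd = read_noise_sd, baseline = baseline,
      bit_depth = as.integer(bit_depth), fov_origin_um = fov_origin_um
    ),
    class = "camera_model"
  )
}

# mu(m) = (ln A - ln m) / k, in m^2/(V s); errors when mass >= A.
mobility_of_mass <- function(mass_kda, channel) {
  mu <- (log(channel$calib_A_kda) - log(mass_kda)) / channel$calib_k
  if (any(mu <= 0)) {
    bad <- mass_kda[mu <= 0][1L]
    abort(sprintf(
      "Species mass %.4g kDa is at or above the calibration ceiling A = %.4g kDa (non-positive mobility).",
      bad, channel$calib_A_kda
    ))
  }
  mu
}

#' Draw per-molecule dye counts and effective masses
#'
#' The number of conjugated dyes on each molecule is Binomial over the
#' species' labelable sites at the labeling efficiency; the effective mass is
#' `bare_mass + n_dyes * delta_m`. Molecules that draw zero dyes are dark
#' (unlabeled protein is invisible): they are flagged and excluded from
#' rendering but retained in the returned table for auditing.
#'
#' @param species Species table, e.g. rows from [species_spec()].
#' @param labeling A [labeling_model()].
#' @param seed Integer seed; `NULL` uses the current RNG stream.
#' @return Tibble with columns `molecule_id`, `species`, `n_dyes`,
#'   `mass_kda`, `dark`.
#' @export
sample_labeling <- function(species, labeling, seed = NULL) {
  stopifnot(inherits(labeling, "labeling_model"))
  species <- as_tibble(species)
  req <- c("name", "bare_mass_kda", "n_label_sites", "copy_number")
  if (!all(req %in% names(species))) {
    abort(sprintf("`species` must have columns %s.", paste(req, collapse = ", ")))
  }
  with_seed(seed, {
    per <- purrr::pmap(species, function(name, bare_mass_kda, n_label_sites,
                                         copy_number, ...) {
      n_dyes <- rbinom(copy_number, size = n_label_sites, prob = labeling$efficiency)
      tibble(
        species = name,
        n_dyes = n_dyes,
        mass_kda = bare_mass_kda + n_dyes * labeling$delta_m_kda
      )
    })
    out <- bind_rows(per)
    out$molecule_id <- seq_len(nrow(out))
    out$dark <- out$n_dyes == 0L
    out[, c("molecule_id", "species", "n_dyes", "mass_kda", "dark")]
  })
}

region_of <- function(x, channel) {
  ifelse(x < channel$gel_start_um, 1L,
         ifelse(x < channel$gel_end_um, 2L, 3L))
}

# Advance drift over one frame interval, resolving region-boundary crossings
# analytically within the step (a molecule that reaches the gel interface
# mid-step continues at the in-gel speed for the remainder of the step).
advance_drift <- function(x, v_gel_umps, dt, channel) {
  t_rem <- rep(dt, length(x))
  for (pass in 1:3) {
    active <- t_rem > 1e-15
    if (!any(active)) break
    reg <- region_of(x, channel)
    v <- ifelse(reg == 1L, channel$v_open_umps,
                ifelse(reg == 2L, v_gel_umps,
                       v_gel_umps * channel$post_gel_speedup))
    bound <- ifelse(reg == 1L, channel$gel_start_um,
                    ifelse(reg == 2L, channel$gel_end_um, Inf))
    t_to_bound <- ifelse(v > 0, (bound - x) / v, Inf)
    step_t <- pmin(t_rem, t_to_bound)
    x <- ifelse(active, x + v * step_t, x)
    crossed <- active & is.finite(bound) & t_to_bound <= t_rem
    x[crossed] <- bound[crossed]
    t_rem <- pmax(ifelse(active, t_rem - step_t, 0), 0)
  }
  x
}

reflect_into <- function(y, width) {
  y <- y %% (2 * width)
  ifelse(y > width, 2 * width - y, y)
}

#' Simulate single-molecule electromigration trajectories
#'
#' Euler-Maruyama integration at the frame interval `dt = 1 / frame_rate`:
#' `x <- x + v(x) dt + sqrt(2 D(x) dt) xi` with standard-normal `xi`. Drift
#' within a step is integrated piecewise across the gel interface and gel
#' exit so that boundary crossings do not overshoot (essential for
#' reproducing plug stacking kinematics). Initial axial positions are uniform
#' over a plug `[gel_start - plug_length, gel_start)`; transverse positions
#' are uniform over the channel width with reflecting walls.
#'
#' @param species Species table (rows from [species_spec()]).
#' @param labeling A [labeling_model()].
#' @param channel A [channel_model()].
#' @param camera A [camera_model()] (supplies frame rate and field of view).
#' @param duration_s Simulated duration in seconds (> 0).
#' @param plug_length_um Injected plug end-to-end length in um (the device
#'   loads ~200 um plugs).
#' @param seed Integer seed.
#' @return An `sm_simulation` list: `trajectories` (one row per labeled
#'   molecule per frame: `molecule_id`, `species`, `n_dyes`, `mass_kda`,
#'   `frame`, `time_s`, `axial_um`, `transverse_um`, `in_fov`), `truth`
#'   (the in-field subset, the rendered ground truth), `audit` (per-molecule
#'   labeling table including dark molecules), and the input models.
#' @export
simulate_trajectories <- function(species, labeling, channel, camera,
                                  duration_s, plug_length_um = 200,
                                  seed = NULL) {
  stopifnot(inherits(channel, "channel_model"), inherits(camera, "camera_model"))
  check_scalar(duration_s, "duration_s", positive = TRUE)
  check_scalar(plug_length_um, "plug_length_um", positive = TRUE)
  with_seed(seed, {
    audit <- sample_labeling(species, labeling, seed = NULL)
    mol <- audit[!audit$dark, , drop = FALSE]
    dt <- 1 / camera$frame_rate
    n_frames <- max(2L, as.integer(floor(duration_s * camera$frame_rate)))
    px_um <- camera$pixel_size_nm / 1000
    fov_lo <- camera$fov_origin_um
    fov_hi <- camera$fov_origin_um + camera$frame_shape[2L] * px_um
    fov_top <- camera$frame_shape[1L] * px_um

    if (nrow(mol) == 0L) {
      traj <- tibble(
        molecule_id = integer(), species = character(), n_dyes = integer(),
        mass_kda = numeric(), frame = integer(), time_s = numeric(),
        axial_um = numeric(), transverse_um = numeric(), in_fov = logical()
      )
      return(structure(list(trajectories = traj, truth = traj, audit = audit,
                            channel = channel, camera = camera,
                            labeling = labeling, n_frames = n_frames),
                       class = "sm_simulation"))
    }

    n <- nrow(mol)
    v_gel <- mobility_of_mass(mol$mass_kda, channel) * channel$field_vpm * 1e6
    x <- runif(n, channel$gel_start_um - plug_length_um, channel$gel_start_um)
    y <- runif(n, 0, channel$width_um)

    xs <- matrix(NA_real_, n, n_frames)
    ys <- matrix(NA_real_, n, n_frames)
    xs[, 1L] <- x
    ys[, 1L] <- y
    for (f in 2:n_frames) {
      x <- advance_drift(x, v_gel, dt, channel)
      d_here <- ifelse(region_of(x, channel) == 2L,
                       channel$d_gel_um2ps, channel$d_open_um2ps)
      sd_step <- sqrt(2 * d_here * dt)
      x <- x + sd_step * rnorm(n)
      y <- reflect_into(y + sd_step * rnorm(n), channel$width_um)
      xs[, f] <- x
      ys[, f] <- y
    }

    traj <- tibble(
      molecule_id = rep(mol$molecule_id, n_frames),
      species = rep(mol$species, n_frames),
      n_dyes = rep(mol$n_dyes, n_frames),
      mass_kda = rep(mol$mass_kda, n_frames),
      frame = rep(0:(n_frames - 1L), each = n),
      axial_um = as.vector(xs),
      transverse_um = as.vector(ys)
    )
    traj$time_s <- traj$frame / camera$frame_rate
    traj$in_fov <- traj$axial_um >= fov_lo & traj$axial_um < fov_hi &
      traj$transverse_um >= 0 & traj$transverse_um < fov_top
    traj <- traj[order(traj$frame, traj$molecule_id),
                 c("molecule_id", "species", "n_dyes", "mass_kda", "frame",
                   "time_s", "axial_um", "transverse_um", "in_fov")]
    structure(
      list(trajectories = traj, truth = traj[traj$in_fov, , drop = FALSE],
           audit = audit, channel = channel, camera = camera,
           labeling = labeling, n_frames = n_frames),
      class = "sm_simulation"
    )
  })
}

#' @export
print.sm_simulation <- function(x, ...) {
  cat("<sm_simulation>\n")
  cat(sprintf("  %d labeled molecules (%d dark excluded), %d frames\n",
              length(unique(x$trajectories$molecule_id)),
              sum(x$audit$dark), x$n_frames))
  invisible(x)
}

# Pixel-integrated isotropic Gaussian PSF: expected photons in pixel i
# (0-based, centred at coordinate i) for a spot centred at `c` px.
psf_pixel_weights <- function(idx, centre, sigma) {
  pnorm(idx + 0.5, centre, sigma) - pnorm(idx - 0.5, centre, sigma)
}

#' Render trajectories into an EMCCD video stack
#'
#' Each visible molecule becomes a 2D isotropic Gaussian of sd
#' `psf_sigma_px` with total expected photons `n_dyes * photons_per_dye`
#' (pixel-integrated, no motion blur within a frame). Pixel values are
#' `baseline + em_gain * Poisson(expected photons) + Normal(0, read_noise_sd)`,
#' rounded and clipped to `[0, 2^bit_depth - 1]`. With `noise = FALSE` the
#' Poisson and read-noise draws are replaced by their expectations (useful
#' for photon-accounting checks).
#'
#' @param sim An `sm_simulation` from [simulate_trajectories()], or a
#'   trajectory tibble with columns `frame`, `axial_um`, `transverse_um`,
#'   `n_dyes`.
#' @param camera A [camera_model()]; defaults to the simulation's camera.
#' @param seed Integer seed for the noise draws.
#' @param noise Logical; draw shot/read noise (default) or render the
#'   noise-free expectation.
#' @param n_frames Number of frames to render; defaults to the trajectory
#'   extent.
#' @return A `frame_stack`: list of integer matrices plus the camera model.
#' @export
render_video <- function(sim, camera = NULL, seed = NULL, noise = TRUE,
                         n_frames = NULL) {
  if (inherits(sim, "sm_simulation")) {
    camera <- camera %||% sim$camera
    traj <- sim$trajectories
    n_frames <- n_frames %||% sim$n_frames
  } else {
    traj <- as_tibble(sim)
    if (is.null(camera)) abort("`camera` must be supplied with a raw trajectory table.")
  }
  stopifnot(inherits(camera, "camera_model"))
  n_frames <- n_frames %||% (if (nrow(traj)) max(traj$frame) + 1L else 1L)
  rows <- camera$frame_shape[1L]
  cols <- camera$frame_shape[2L]
  px_um <- camera$pixel_size_nm / 1000
  sig <- camera$psf_sigma_px
  rad <- ceiling(5 * sig)
  vmax <- 2^camera$bit_depth - 1

  with_seed(seed, {
    frames <- vector("list", n_frames)
    traj_by_frame <- split(traj, factor(traj$frame, levels = 0:(n_frames - 1L)))
    for (f in seq_len(n_frames)) {
      lambda <- matrix(0, rows, cols)
      tf <- traj_by_frame[[f]]
      if (!is.null(tf) && nrow(tf)) {
        cc <- (tf$axial_um - camera$fov_origin_um) / px_um
        rr <- tf$transverse_um / px_um
        keep <- cc > -rad & cc < cols - 1 + rad & rr > -rad & rr < rows - 1 + rad
        for (i in which(keep)) {
          ci <- max(0L, floor(cc[i] - rad)):min(cols - 1L, ceiling(cc[i] + rad))
          ri <- max(0L, floor(rr[i] - rad)):min(rows - 1L, ceiling(rr[i] + rad))
          if (!length(ci) || !length(ri)) next
          w <- outer(psf_pixel_weights(ri, rr[i], sig),
                     psf_pixel_weights(ci, cc[i], sig))
          lambda[ri + 1L, ci + 1L] <- lambda[ri + 1L, ci + 1L] +
            tf$n_dyes[i] * camera$photons_per_dye * w
        }
      }
      if (noise) {
        photons <- matrix(rpois(rows * cols, lambda), rows, cols)
        img <- camera$baseline + camera$em_gain * photons +
          matrix(rnorm(rows * cols, 0, camera$read_noise_sd), rows, cols)
      } else {
        img <- camera$baseline + camera$em_gain * lambda
      }
      img <- round(pmin(pmax(img, 0), vmax))
      storage.mode(img) <- "integer"
      frames[[f]] <- img
    }
    structure(list(frames = frames, camera = camera, n_frames = n_frames),
              class = "frame_stack")
  })
}

#' @export
print.frame_stack <- function(x, ...) {
  cat(sprintf("<frame_stack> %d frames of %d x %d px, %.2f fps, %g nm/px\n",
              x$n_frames, nrow(x$frames[[1L]]), ncol(x$frames[[1L]]),
              x$camera$frame_rate, x$camera$pixel_size_nm))
  invisible(x)
}

#' Write a simulated dataset to disk
#'
#' Writes the video as a multi-page 16-bit grayscale TIFF, the ground truth
#' as CSV (`molecule_id,species,n_dyes,mass_kda,frame,axial_um,transverse_um`)
#' and a YAML config snapshot sufficient to regenerate the dataset with the
#' same seed.
#'
#' @param stack A `frame_stack` from [render_video()].
#' @param truth Ground-truth tibble (e.g. `sim$truth`).
#' @param out_dir Output directory (created if missing).
#' @param config Optional named list written as `config.yaml`.
#' @return Named character vector of written paths.
#' @export
write_dataset <- function(stack, truth, out_dir, config = NULL) {
  stopifnot(inherits(stack, "frame_stack"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) abort(sprintf("Cannot create directory '%s'.", out_dir))
  vmax <- 2^stack$camera$bit_depth - 1
  tif <- file.path(out_dir, "stack.tif")
  tiff::writeTIFF(lapply(stack$frames, function(m) m / vmax), tif,
                  bits.per.sample = 16L)
  truth_csv <- file.path(out_dir, "truth.csv")
  cols <- c("molecule_id", "species", "n_dyes", "mass_kda", "frame",
            "axial_um", "transverse_um")
  write.csv(as.data.frame(truth)[, intersect(cols, names(truth))],
            truth_csv, row.names = FALSE)
  cfg <- file.path(out_dir, "config.yaml")
  snapshot <- config %||% list()
  snapshot$camera <- unclass(stack$camera)
  yaml::write_yaml(snapshot, cfg)
  c(stack = tif, truth = truth_csv, config = cfg)
}

#' Read a dataset written by [write_dataset()]
#'
#' @param dir Dataset directory.
#' @return List with `stack` (a `frame_stack`) and `truth` (tibble; `NULL`
#'   when absent).
#' @export
read_dataset <- function(dir) {
  tif <- file.path(dir, "stack.tif")
  if (!file.exists(tif)) abort(sprintf("No stack.tif under '%s'.", dir))
  pages <- tiff::readTIFF(tif, all = TRUE, as.is = TRUE)
  if (is.matrix(pages)) pages <- list(pages)
  cfg_path <- file.path(dir, "config.yaml")
  camera <- camera_model()
  if (file.exists(cfg_path)) {
    cfg <- yaml::read_yaml(cfg_path)
    if (!is.null(cfg$camera)) {
      cam_args <- cfg$camera[intersect(names(cfg$camera), names(formals(camera_model)))]
      cam_args$frame_shape <- unlist(cam_args$frame_shape)
      camera <- do.call(camera_model, cam_args)
    }
  }
  truth_path <- file.path(dir, "truth.csv")
  truth <- if (file.exists(truth_path)) as_tibble(read.csv(truth_path)) else NULL
  list(
    stack = structure(list(frames = pages, camera = camera,
                           n_frames = length(pages)),
                      class = "frame_stack"),
    truth = truth
  )
}
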