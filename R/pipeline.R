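#' Validate and normalise a pipeline configuration
#'
#' Reads a YAML file (or takes a named list), checks it against the known
#' stage blocks, fills defaults encoding the standard acquisition regime
#' (267 nm pixels, 19.31 fps, 5 s bins, kymograph column 256, 12 kV/m), and
#' checks unit-bearing fields for positivity. Unknown keys raise an error
#' listing them; a missing or empty file yields a configuration of pure
#' defaults.
#'
#' @param config Path to a YAML file, a YAML string, or a named list.
#' @return A `pipeline_config` list with blocks `acquisition`, `simulate`,
#'   `detect`, `kymograph`, `quantify`, `track`, `calibrate`, plus `seed`
#'   and `out_dir`.
#' @export
validate_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1L) {
    config <- if (file.exists(config)) {
      yaml::read_yaml(config) %||% list()
    } else {
      yaml::yaml.load(config) %||% list()
    }
  }
  if (!is.list(config)) abort("`config` must be a YAML file/string or a list.")

  defaults <- list(
    acquisition = list(
      pixel_size_nm = 267, frame_rate = 19.31, field_vpm = 12e3,
      travel_distance_mm = 2.3, kymo_column = 256L
    ),
    simulate = NULL,
    detect = list(log_sigma = 1.5, k_threshold = 5, min_area = 2L,
                  connectivity = 8L),
    kymograph = list(threshold = NULL),
    quantify = list(bin_width_s = 5, t_reference_s = 0,
                    min_separation_s = 10, min_height = 1),
    track = list(max_disp_px = 10, boundary_col = NULL),
    calibrate = NULL,
    seed = 1L,
    out_dir = "smsep_run"
  )
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown)) {
    abort(sprintf("Unknown config keys: %s.", paste(unknown, collapse = ", ")))
  }
  merged <- defaults
  for (key in names(config)) {
    blk <- config[[key]]
    if (is.list(blk) && is.list(defaults[[key]])) {
      unk <- setdiff(names(blk), names(defaults[[key]]))
      if (length(unk)) {
        abort(sprintf("Unknown keys in `%s`: %s.", key, paste(unk, collapse = ", ")))
      }
      merged[[key]] <- utils::modifyList(defaults[[key]], blk)
    } else {
      merged[[key]] <- blk
    }
  }
  acq <- merged$acquisition
  for (fld in c("pixel_size_nm", "frame_rate", "field_vpm", "travel_distance_mm")) {
    if (is.null(acq[[fld]])) abort(sprintf("Config is missing `acquisition.%s`.", fld))
    check_scalar(acq[[fld]], paste0("acquisition.", fld), positive = TRUE)
  }
  if (acq$kymo_column < 0) abort("`acquisition.kymo_column` must be >= 0.")
  structure(merged, class = "pipeline_config")
}

write_stage_csv <- function(df, path) {
  write.csv(as.data.frame(df), path, row.names = FALSE)
  path
}

#' Run the full separation pipeline
#'
#' Orchestrates simulate -> detect -> kymograph -> quantify -> track ->
#' calibrate as one reproducible run. Each stage writes its outputs under
#' `out_dir`; a JSON manifest (config hash, package version, per-stage
#' outputs, seed, timestamps) is written last. A stage failure aborts with
#' the failing stage named; outputs of completed stages are preserved.
#'
#' @param config A `pipeline_config` from [validate_config()] (or anything
#'   it accepts).
#' @return The manifest, invisibly (also written to
#'   `out_dir/manifest.json`).
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) config <- validate_config(config)
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  acq <- config$acquisition
  manifest <- list(
    package = "smsep",
    version = as.character(utils::packageVersion("smsep")),
    seed = config$seed,
    started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    stages = list()
  )
  cfg_path <- file.path(out_dir, "config.yaml")
  yaml::write_yaml(unclass(config), cfg_path)
  manifest$config_hash <- unname(tools::md5sum(cfg_path))

  run_stage <- function(name, fun) {
    tryCatch(fun(), error = function(e) {
      abort(sprintf("Pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }

  stack <- NULL
  truth <- NULL
  camera <- NULL

  if (!is.null(config$simulate)) {
    sim_out <- run_stage("simulate", function() {
      sc <- config$simulate
      camera <- do.call(camera_model, c(
        list(pixel_size_nm = acq$pixel_size_nm, frame_rate = acq$frame_rate),
        sc$camera %||% list()
      ))
      channel <- do.call(channel_model, c(list(field_vpm = acq$field_vpm),
                                          sc$channel %||% list()))
      labeling <- do.call(labeling_model, sc$labeling %||% list())
      species <- bind_rows(purrr::map(sc$species, function(s) do.call(species_spec, s)))
      sim <- simulate_trajectories(
        species, labeling, channel, camera,
        duration_s = sc$duration_s,
        plug_length_um = sc$plug_length_um %||% 200,
        seed = config$seed
      )
      stack <- render_video(sim, seed = config$seed + 1L)
      paths <- write_dataset(stack, sim$truth, out_dir, config = unclass(config))
      list(stack = stack, truth = sim$truth, camera = camera, paths = paths)
    })
    stack <- sim_out$stack
    truth <- sim_out$truth
    camera <- sim_out$camera
    manifest$stages$simulate <- as.list(sim_out$paths)
  } else {
    if (is.null(config$input_stack) && !file.exists(file.path(out_dir, "stack.tif"))) {
      abort("Config has no `simulate` block and no existing stack to analyse.")
    }
    ds <- run_stage("load", function() read_dataset(out_dir))
    stack <- ds$stack
    truth <- ds$truth
    camera <- stack$camera
  }

  det_params <- do.call(detection_params, config$detect)
  particles <- run_stage("detect", function() detect_stack(stack, det_params))
  p_path <- write_stage_csv(particles, file.path(out_dir, "particles.csv"))
  manifest$stages$detect <- list(particles = p_path, n_particles = nrow(particles))

  kymo_col <- min(acq$kymo_column, ncol(stack$frames[[1L]]) - 1L)
  kymo <- run_stage("kymograph", function() build_kymograph(stack, kymo_col))
  kp <- run_stage("kymograph", function() detect_particles(kymo$data, det_params))
  trace <- fraction_above_threshold(kymo, config$kymograph$threshold)
  t_path <- write_stage_csv(trace, file.path(out_dir, "kymo_trace.csv"))
  manifest$stages$kymograph <- list(trace = t_path, column = kymo_col,
                                    n_kymo_particles = nrow(kp))

  qc <- config$quantify
  ep <- run_stage("quantify", function() {
    arrival_histogram(kp, camera$frame_rate, qc$bin_width_s, qc$t_reference_s)
  })
  peaks <- run_stage("quantify", function() {
    if (nrow(ep$bins) < 3L) {
      tibble(time_s = numeric(), height = integer(), n_particles = integer(),
             left_s = numeric(), right_s = numeric())
    } else {
      find_peaks(ep, qc$min_separation_s, qc$min_height)
    }
  })
  ep_path <- write_stage_csv(ep$bins, file.path(out_dir, "electropherogram.csv"))
  pk_path <- write_stage_csv(peaks, file.path(out_dir, "peaks.csv"))
  manifest$stages$quantify <- list(electropherogram = ep_path, peaks = pk_path,
                                   n_peaks = nrow(peaks))

  tracks <- run_stage("track", function() {
    link_particles(particles, config$track$max_disp_px)
  })
  tr_path <- write_stage_csv(tracks, file.path(out_dir, "tracks.csv"))
  manifest$stages$track <- list(tracks = tr_path,
                                n_tracks = length(unique(tracks$track_id)))
  if (!is.null(config$track$boundary_col)) {
    vp <- run_stage("track", function() {
      velocity_populations(tracks, config$track$boundary_col,
                           camera$pixel_size_nm, camera$frame_rate)
    })
    vp_json <- file.path(out_dir, "velocity_stats.json")
    jsonlite::write_json(list(in_gel = vp$in_gel, post_gel = vp$post_gel,
                              fold_change = vp$fold_change),
                         vp_json, auto_unbox = TRUE, digits = NA)
    manifest$stages$track$velocity_stats <- vp_json
  }

  if (!is.null(config$calibrate) && nrow(peaks) >= 3L) {
    cal <- run_stage("calibrate", function() {
      cc <- config$calibrate
      masses <- unlist(cc$ladder_masses_kda)
      pk <- head(arrange(peaks, dplyr::desc(.data$height)), length(masses))
      pk <- arrange(pk, .data$time_s)
      if (nrow(pk) < 3L) abort("Fewer than 3 peaks available for calibration.")
      mu <- mobility(acq$travel_distance_mm / 1000, pk$time_s,
                     cc$t_dye_s %||% 0, acq$field_vpm)
      fit_exponential(mu, sort(masses, decreasing = FALSE)[seq_len(nrow(pk))],
                      efficiency_assumed = cc$efficiency %||% NA_real_)
    })
    cal_json <- file.path(out_dir, "calibration.json")
    jsonlite::write_json(
      list(A_kda = cal$A_kda, k = cal$k, r_squared = cal$r_squared,
           chi_squared = cal$chi_squared,
           efficiency_assumed = cal$efficiency_assumed,
           points = cal$points),
      cal_json, auto_unbox = TRUE, digits = NA
    )
    manifest$stages$calibrate <- list(calibration = cal_json)
  }

  manifest$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  man_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, man_path, auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
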