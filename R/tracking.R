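#' Link per-frame detections into tracks
#'
#' Greedy nearest-neighbour linking: for each frame transition, candidate
#' (track, detection) pairs within `max_disp_px` are assigned in order of
#' ascending distance; unmatched detections start new tracks. A single
#' missed frame is bridged: an unmatched track survives one frame with its
#' position extrapolated by its last displacement, then closes. Adequate at
#' the low occupancies this device is designed for; no global assignment or
#' multi-hypothesis tracking is attempted.
#'
#' @param particles Detections tibble (`frame`, `row`, `col`, optionally
#'   `energy`, `area`), frames 0-based.
#' @param max_disp_px Maximum frame-to-frame displacement in px. A sensible
#'   default is 3x the expected per-frame drift.
#' @return The input rows with a `track_id` column, sorted by
#'   `(track_id, frame)`.
#' @export
link_particles <- function(particles, max_disp_px) {
  check_scalar(max_disp_px, "max_disp_px", positive = TRUE)
  p <- as_tibble(particles)
  if (nrow(p) == 0L) {
    p$track_id <- integer()
    return(p)
  }
  p <- p[order(p$frame), , drop = FALSE]
  p$track_id <- NA_integer_
  frames <- sort(unique(p$frame))
  next_id <- 1L
  # active tracks: id, pred_row, pred_col, vel_row, vel_col, last_frame, missed
  active <- tibble(id = integer(), row = numeric(), col = numeric(),
                   vrow = numeric(), vcol = numeric(),
                   last_frame = integer(), missed = integer())
  for (f in frames) {
    di <- which(p$frame == f)
    det <- p[di, , drop = FALSE]
    assigned_det <- rep(FALSE, nrow(det))
    matched_tracks <- integer()
    if (nrow(active)) {
      gap <- f - active$last_frame
      pred_row <- active$row + active$vrow * gap
      pred_col <- active$col + active$vcol * gap
      dmat <- sqrt(outer(pred_row, det$row, `-`)^2 +
                   outer(pred_col, det$col, `-`)^2)
      pairs <- which(dmat <= max_disp_px, arr.ind = TRUE)
      if (nrow(pairs)) {
        pairs <- pairs[order(dmat[pairs]), , drop = FALSE]
        used_t <- rep(FALSE, nrow(active))
        for (k in seq_len(nrow(pairs))) {
          ti <- pairs[k, 1L]
          dj <- pairs[k, 2L]
          if (used_t[ti] || assigned_det[dj]) next
          used_t[ti] <- TRUE
          assigned_det[dj] <- TRUE
          id <- active$id[ti]
          p$track_id[di[dj]] <- id
          gap_k <- f - active$last_frame[ti]
          active$vrow[ti] <- (det$row[dj] - active$row[ti]) / gap_k
          active$vcol[ti] <- (det$col[dj] - active$col[ti]) / gap_k
          active$row[ti] <- det$row[dj]
          active$col[ti] <- det$col[dj]
          active$last_frame[ti] <- f
          active$missed[ti] <- 0L
          matched_tracks <- c(matched_tracks, ti)
        }
      }
    }
    # age unmatched tracks, drop after more than one missed frame
    if (nrow(active)) {
      unmatched <- setdiff(seq_len(nrow(active)), matched_tracks)
      active$missed[unmatched] <- active$missed[unmatched] +
        (f - active$last_frame[unmatched] > 0L)
      active <- active[active$missed <= 1L & f - active$last_frame <= 2L, ,
                       drop = FALSE]
    }
    # new tracks from unassigned detections
    for (dj in which(!assigned_det)) {
      p$track_id[di[dj]] <- next_id
      active <- bind_rows(active, tibble(
        id = next_id, row = det$row[dj], col = det$col[dj],
        vrow = 0, vcol = 0, last_frame = f, missed = 0L
      ))
      next_id <- next_id + 1L
    }
  }
  p[order(p$track_id, p$frame), , drop = FALSE]
}

#' Velocity of one track
#'
#' Least-squares slope of axial position (um, from the `col` coordinate)
#' against time (s). Tracks with fewer than 3 points are rejected.
#'
#' @param track Tibble with `frame` and `col` (one track).
#' @param pixel_size_nm Pixel size in nm.
#' @param frame_rate Frames per second.
#' @return Velocity in um/s (positive along the field direction).
#' @examples
#' tr <- tibble::tibble(frame = 0:9, col = 2 * (0:9))
#' track_velocity(tr, 267, 19.31) # 2 px/frame = 10.31 um/s
#' @export
track_velocity <- function(track, pixel_size_nm = 267, frame_rate = 19.31) {
  if (nrow(track) < 3L) {
    abort("A track needs at least 3 points for a velocity estimate.")
  }
  t_s <- track$frame / frame_rate
  x_um <- track$col * pixel_size_nm / 1000
  unname(coef(lm(x_um ~ t_s))[2L])
}

#' Per-track velocities for a linked set
#'
#' @param tracks Output of [link_particles()].
#' @inheritParams track_velocity
#' @return Tibble `track_id, n_points, velocity_umps`; tracks with fewer
#'   than 3 points are excluded.
#' @export
track_velocities <- function(tracks, pixel_size_nm = 267, frame_rate = 19.31) {
  pieces <- split(as_tibble(tracks), tracks$track_id)
  pieces <- pieces[vapply(pieces, nrow, integer(1)) >= 3L]
  if (!length(pieces)) {
    return(tibble(track_id = integer(), n_points = integer(),
                  velocity_umps = numeric()))
  }
  tibble(
    track_id = as.integer(names(pieces)),
    n_points = vapply(pieces, nrow, integer(1)),
    velocity_umps = vapply(pieces, track_velocity, numeric(1),
                           pixel_size_nm = pixel_size_nm,
                           frame_rate = frame_rate)
  ) |> arrange(.data$track_id)
}

velocity_stats <- function(v) {
  list(mean = mean(v), sd = stats::sd(v),
       sem = stats::sd(v) / sqrt(length(v)), n = length(v))
}

#' In-gel versus post-gel velocity populations
#'
#' Splits each track at the gel exit (`boundary_col`, marked manually on the
#' images): points at or before the boundary form the in-gel segment, points
#' beyond it the post-gel segment, and the displacement interval straddling
#' the boundary belongs to neither. Per-segment velocities (segments with at
#' least 3 points) are pooled into the two populations and the fold change
#' of the mean velocities is reported; on gel exit proteins accelerate
#' roughly 70-fold.
#'
#' @param tracks Output of [link_particles()].
#' @param boundary_col 0-based column of the gel exit.
#' @inheritParams track_velocity
#' @return A `velocity_populations` list: `in_gel` and `post_gel` (each
#'   `mean`, `sd`, `sem`, `n` in um/s) and `fold_change`.
#' @export
velocity_populations <- function(tracks, boundary_col, pixel_size_nm = 267,
                                 frame_rate = 19.31) {
  check_scalar(boundary_col, "boundary_col", nonneg = TRUE)
  seg_vel <- function(seg_tracks) {
    if (nrow(seg_tracks) == 0L) return(numeric())
    track_velocities(seg_tracks, pixel_size_nm, frame_rate)$velocity_umps
  }
  in_gel <- seg_vel(filter(tracks, .data$col <= boundary_col))
  post <- seg_vel(filter(tracks, .data$col > boundary_col))
  if (!length(in_gel)) abort("No usable in-gel track segments.")
  if (!length(post)) abort("No usable post-gel track segments.")
  sin_ <- velocity_stats(in_gel)
  spost <- velocity_stats(post)
  structure(
    list(in_gel = sin_, post_gel = spost,
         fold_change = spost$mean / sin_$mean),
    class = "velocity_populations"
  )
}

#' @export
print.velocity_populations <- function(x, ...) {
  cat("<velocity_populations>\n")
  cat(sprintf("  in-gel : %.3g +/- %.2g um/s (sem, n = %d)\n",
              x$in_gel$mean, x$in_gel$sem, x$in_gel$n))
  cat(sprintf("  post   : %.3g +/- %.2g um/s (sem, n = %d)\n",
              x$post_gel$mean, x$post_gel$sem, x$post_gel$n))
  cat(sprintf("  fold change: %.3g x\n", x$fold_change))
  invisible(x)
}

#' @rdname velocity_populations
#' @param x A `velocity_populations` object.
#' @param ... Unused.
#' @export
tidy.velocity_populations <- function(x, ...) {
  bind_rows(
    tibble(population = "in_gel", mean = x$in_gel$mean, sd = x$in_gel$sd,
           sem = x$in_gel$sem, n = x$in_gel$n),
    tibble(population = "post_gel", mean = x$post_gel$mean,
           sd = x$post_gel$sd, sem = x$post_gel$sem, n = x$post_gel$n)
  )
}

#' @rdname velocity_populations
#' @export
glance.velocity_populations <- function(x, ...) {
  tibble(fold_change = x$fold_change, n_in_gel = x$in_gel$n,
         n_post_gel = x$post_gel$n)
}
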