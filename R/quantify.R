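#' Arrival-time electropherogram from kymograph detections
#'
#' Converts particles detected on a kymograph into an arrival-time histogram
#' (the single-molecule analogue of a gel densitogram). Each particle's time
#' is `col / frame_rate - t_reference`; the reference is conventionally the
#' end of the free-fluorophore front so that `t = 0` marks the fastest
#' population. Negative (pre-reference) times are retained in an underflow
#' count, not dropped.
#'
#' @param particles Tibble with a `col` column (kymograph detections from
#'   [detect_particles()]).
#' @param frame_rate Frames per second.
#' @param bin_width_s Bin width in seconds (default 5).
#' @param t_reference Reference time subtracted from all arrivals, seconds.
#' @return An `electropherogram`: list with `bins` (tibble `bin_start_s,
#'   bin_end_s, count`), `bin_width_s`, `t_reference_s`, `underflow`,
#'   `times_s` (per-particle relative times).
#' @export
arrival_histogram <- function(particles, frame_rate, bin_width_s = 5,
                              t_reference = 0) {
  check_scalar(frame_rate, "frame_rate", positive = TRUE)
  if (bin_width_s <= 0) abort("`bin_width_s` must be > 0.")
  times <- arrival_time(particles$col, frame_rate) - t_reference
  pos <- times[times >= 0]
  n_bins <- if (length(pos)) max(1L, ceiling((max(pos) + 1e-9) / bin_width_s)) else 1L
  edges <- seq(0, n_bins * bin_width_s, by = bin_width_s)
  counts <- if (length(pos)) {
    tabulate(pmin(floor(pos / bin_width_s) + 1L, n_bins), nbins = n_bins)
  } else {
    integer(n_bins)
  }
  structure(
    list(
      bins = tibble(bin_start_s = edges[-length(edges)],
                    bin_end_s = edges[-1L],
                    count = as.integer(counts)),
      bin_width_s = bin_width_s,
      t_reference_s = t_reference,
      underflow = sum(times < 0),
      times_s = times
    ),
    class = "electropherogram"
  )
}

#' @export
print.electropherogram <- function(x, ...) {
  cat(sprintf(
    "<electropherogram> %d particles in %d bins of %g s (t_ref = %g s, %d pre-reference)\n",
    sum(x$bins$count), nrow(x$bins), x$bin_width_s, x$t_reference_s, x$underflow))
  invisible(x)
}

#' Digital molecule counting through a non-overlapping stripe
#'
#' Counts molecules from full frame-stack detections without double
#' counting: a fixed axial stripe of width `w = max(1, floor(drift))` px is
#' examined in every frame, and a detection is accepted only in the frame it
#' first enters the stripe. Because the per-frame migration distance is at
#' least the stripe width, successive frames sample non-overlapping regions
#' of the channel for a drifting molecule. Near-stationary duplicates
#' (diffusive jitter) are suppressed by rejecting candidates closer than
#' `dedup_radius` px to an accepted detection in the previous frame. A
#' molecule that genuinely re-enters the stripe (e.g. a reflected
#' trajectory) is counted again; that is inherent to stripe semantics.
#' When the drift has a fractional pixel part the integer stripe width
#' undercounts by roughly that fraction of the drift (molecules can jump the
#' stripe between frames); estimate the drift so it is close to a whole
#' number of pixels per frame where possible.
#'
#' @param particles Frame-stack detections (`frame`, `row`, `col`).
#' @param drift_px_per_frame Typical migration distance per frame, px (> 0).
#' @param stripe_col 0-based column of the stripe's left edge.
#' @param frame_rate Frames per second (for arrival times).
#' @param frame_width Total frame width in px, used to validate the stripe;
#'   default: no validation beyond the particle extent.
#' @param dedup_radius Radius in px for suppressing repeats from the
#'   previous frame; default 0.5 px, about twice the per-frame diffusive
#'   jitter of a gel-embedded molecule (a drifting molecule moves a full
#'   stripe width between frames and is never this close to its previous
#'   position, so only lingering molecules are suppressed).
#' @return List with `unique_count` and `arrivals` (tibble `frame, time_s,
#'   row, col`).
#' @export
count_frame_stack <- function(particles, drift_px_per_frame, stripe_col,
                              frame_rate = 19.31, frame_width = NULL,
                              dedup_radius = NULL) {
  check_scalar(drift_px_per_frame, "drift_px_per_frame", positive = TRUE)
  w <- max(1, floor(drift_px_per_frame))
  if (stripe_col < 0 ||
      (!is.null(frame_width) && stripe_col + w > frame_width)) {
    abort("The stripe lies outside the frame.")
  }
  dedup_radius <- dedup_radius %||% 0.5
  inside <- particles$col >= stripe_col & particles$col < stripe_col + w
  cand <- particles[inside, , drop = FALSE]
  if (nrow(cand) == 0L) {
    return(list(unique_count = 0L,
                arrivals = tibble(frame = integer(), time_s = numeric(),
                                  row = numeric(), col = numeric())))
  }
  cand <- cand[order(cand$frame), , drop = FALSE]
  accepted <- vector("list", length(unique(cand$frame)))
  prev <- NULL
  for (i in seq_along(accepted)) {
    f <- unique(cand$frame)[i]
    cf <- cand[cand$frame == f, , drop = FALSE]
    if (!is.null(prev) && prev$frame[1L] == f - 1L && nrow(prev)) {
      keep <- vapply(seq_len(nrow(cf)), function(j) {
        d2 <- (cf$row[j] - prev$row)^2 + (cf$col[j] - prev$col)^2
        all(d2 > dedup_radius^2)
      }, logical(1))
      acc <- cf[keep, , drop = FALSE]
    } else {
      acc <- cf
    }
    accepted[[i]] <- acc
    prev <- cf # compare against everything seen in the stripe last frame
  }
  arr <- bind_rows(accepted)
  arr <- tibble(frame = as.integer(arr$frame),
                time_s = arr$frame / frame_rate,
                row = arr$row, col = arr$col)
  list(unique_count = nrow(arr), arrivals = arr)
}

#' Find migration peaks in an electropherogram
#'
#' Local maxima of the binned counts above `min_height`; peaks closer than
#' `min_separation_s` are merged keeping the taller (earlier on ties). Peak
#' regions are delimited by the enclosing local minima between neighbouring
#' peaks (histogram ends at the extremes), and `n_particles` sums the counts
#' in the region, enabling digital per-peak protein counting.
#'
#' @param ep An `electropherogram` from [arrival_histogram()].
#' @param min_separation_s Minimum peak separation in seconds.
#' @param min_height Minimum peak height in counts per bin.
#' @return Tibble `time_s, height, n_particles, left_s, right_s` sorted by
#'   time; zero rows when nothing qualifies.
#' @export
find_peaks <- function(ep, min_separation_s = 10, min_height = 1) {
  stopifnot(inherits(ep, "electropherogram"))
  counts <- ep$bins$count
  nb <- length(counts)
  if (nb < 3L) abort("The electropherogram must have at least 3 bins.")
  centres <- (ep$bins$bin_start_s + ep$bins$bin_end_s) / 2
  padded <- c(-Inf, counts, -Inf)
  is_max <- vapply(seq_len(nb), function(i) {
    padded[i + 1L] >= padded[i] && padded[i + 1L] >= padded[i + 2L]
  }, logical(1))
  # keep only the first bin of a plateau
  plateau_repeat <- c(FALSE, counts[-1L] == counts[-nb]) & is_max
  cand <- which(is_max & !plateau_repeat & counts >= min_height)
  if (!length(cand)) {
    return(tibble(time_s = numeric(), height = integer(),
                  n_particles = integer(), left_s = numeric(),
                  right_s = numeric()))
  }
  # merge peaks closer than min_separation_s, keeping the taller (tie: earlier)
  ord <- cand[order(-counts[cand], centres[cand])]
  kept <- integer()
  for (i in ord) {
    if (all(abs(centres[i] - centres[kept]) >= min_separation_s) || !length(kept)) {
      kept <- c(kept, i)
    }
  }
  kept <- sort(kept)
  # partition bins at the minima between consecutive peaks (min bin goes left)
  cuts <- integer(length(kept) + 1L)
  cuts[1L] <- 0L
  cuts[length(kept) + 1L] <- nb
  if (length(kept) > 1L) {
    for (j in seq_len(length(kept) - 1L)) {
      seg <- (kept[j] + 1L):(kept[j + 1L] - 1L)
      cuts[j + 1L] <- if (length(seg)) seg[which.min(counts[seg])] else kept[j]
    }
  }
  out <- purrr::map(seq_along(kept), function(j) {
    lo <- cuts[j] + 1L
    hi <- cuts[j + 1L]
    tibble(
      time_s = centres[kept[j]],
      height = as.integer(counts[kept[j]]),
      n_particles = as.integer(sum(counts[lo:hi])),
      left_s = ep$bins$bin_start_s[lo],
      right_s = ep$bins$bin_end_s[hi]
    )
  })
  bind_rows(out)
}

#' Time-resolved normalized intensity histograms
#'
#' Particle energies are normalized to the maximum particle energy in their
#' own frame (so frames are comparable), then histogrammed on `[0, 1]`
#' within each requested time window. Later windows of a separation shift
#' towards higher normalized intensities: heavier, more-labeled proteins
#' arrive late.
#'
#' @param particles Frame-stack detections (`frame`, `energy`).
#' @param time_windows Tibble or data frame with columns `start_s`, `end_s`;
#'   windows must be disjoint.
#' @param frame_rate Frames per second.
#' @param n_bins Number of histogram bins on `[0, 1]`.
#' @return An `intensity_histograms` list: `windows` (with `n_particles` and
#'   `empty` flag) and `histograms` (tibble `window_id, bin_left, bin_right,
#'   count`).
#' @export
intensity_histograms <- function(particles, time_windows, frame_rate = 19.31,
                                 n_bins = 20L) {
  tw <- as_tibble(time_windows)
  if (!all(c("start_s", "end_s") %in% names(tw))) {
    abort("`time_windows` needs columns `start_s` and `end_s`.")
  }
  o <- order(tw$start_s)
  if (any(tw$end_s[o][-nrow(tw)] > tw$start_s[o][-1L])) {
    abort("`time_windows` must be disjoint.")
  }
  p <- as_tibble(particles) |>
    group_by(.data$frame) |>
    mutate(norm_energy = .data$energy / max(.data$energy)) |>
    ungroup() |>
    mutate(time_s = .data$frame / frame_rate)
  edges <- seq(0, 1, length.out = n_bins + 1L)
  hists <- purrr::map(seq_len(nrow(tw)), function(i) {
    sel <- p$time_s >= tw$start_s[i] & p$time_s < tw$end_s[i]
    e <- p$norm_energy[sel]
    counts <- if (length(e)) {
      tabulate(pmin(findInterval(e, edges, rightmost.closed = TRUE), n_bins),
               nbins = n_bins)
    } else {
      integer(n_bins)
    }
    tibble(window_id = i, bin_left = edges[-(n_bins + 1L)],
           bin_right = edges[-1L], count = as.integer(counts),
           n_window = length(e))
  })
  hist_tbl <- bind_rows(hists)
  windows <- tw
  windows$window_id <- seq_len(nrow(tw))
  windows$n_particles <- vapply(hists, function(h) h$n_window[1L], integer(1))
  windows$empty <- windows$n_particles == 0L
  structure(
    list(windows = windows[, c("window_id", "start_s", "end_s",
                               "n_particles", "empty")],
         histograms = hist_tbl[, c("window_id", "bin_left", "bin_right",
                                   "count")]),
    class = "intensity_histograms"
  )
}

#' @export
print.intensity_histograms <- function(x, ...) {
  cat(sprintf("<intensity_histograms> %d windows (%d empty)\n",
              nrow(x$windows), sum(x$windows$empty)))
  invisible(x)
}
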