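#' Build a kymograph from a fixed pixel column
#'
#' A kymograph stacks one fixed pixel column of every frame side by side:
#' row `i`, column `j` of the kymograph is pixel `(i, column_index)` of
#' frame `j`. Raw counts are kept unmodified; any dynamic-range rescaling is
#' display-only (see [autoplot.kymograph()]). The conventional column for
#' 512-px frames is the central one, index 256.
#'
#' @param stack A `frame_stack`, list of matrices, or single matrix.
#' @param column_index 0-based column to sample (default 256).
#' @param frame_rate Frames per second; defaults to the stack's camera.
#' @param location_mm Optional physical position of the sampled column along
#'   the channel, in mm (metadata only).
#' @return A `kymograph`: list with `data` (rows x frames matrix),
#'   `column_index`, `frame_rate`, `location_mm`.
#' @export
build_kymograph <- function(stack, column_index = 256L, frame_rate = NULL,
                            location_mm = NA_real_) {
  frames <- as_frame_list(stack)
  nc <- ncol(frames[[1L]])
  if (column_index < 0L || column_index >= nc) {
    abort(sprintf("`column_index` %d is outside the frame width [0, %d).",
                  column_index, nc))
  }
  frame_rate <- stack_frame_rate(stack, frame_rate)
  data <- vapply(frames, function(m) as.numeric(m[, column_index + 1L]),
                 numeric(nrow(frames[[1L]])))
  structure(
    list(data = matrix(data, nrow = nrow(frames[[1L]])),
         column_index = as.integer(column_index),
         frame_rate = frame_rate, location_mm = location_mm),
    class = "kymograph"
  )
}

#' @export
print.kymograph <- function(x, ...) {
  cat(sprintf("<kymograph> %d px x %d frames (column %d, %.2f fps)\n",
              nrow(x$data), ncol(x$data), x$column_index, x$frame_rate))
  invisible(x)
}

#' Fraction of pixels above a threshold, per time column
#'
#' The normalized fluorescence trace used on kymographs: for each time
#' column, the fraction of pixels whose raw count exceeds `threshold`.
#'
#' @param kymo A `kymograph`.
#' @param threshold Counts threshold (>= 0). Default: background level plus
#'   5 robust sds of the kymograph, via [estimate_background()].
#' @return Tibble `time_s, fraction` with one row per frame; fractions lie
#'   in `[0, 1]`.
#' @export
fraction_above_threshold <- function(kymo, threshold = NULL) {
  stopifnot(inherits(kymo, "kymograph"))
  if (is.null(threshold)) {
    bg <- estimate_background(kymo$data)
    threshold <- bg$level + 5 * if (bg$spread > 0) bg$spread else 1
  }
  if (threshold < 0) abort("`threshold` must be >= 0.")
  frac <- colMeans(kymo$data > threshold)
  tibble(time_s = (seq_len(ncol(kymo$data)) - 1L) / kymo$frame_rate,
         fraction = frac)
}

#' Arrival time from a kymograph column coordinate
#'
#' A particle detected on a kymograph has its centre-of-gravity column along
#' the time axis; dividing by the frame rate converts it to the arrival time
#' in seconds. Fractional (subpixel) columns are kept fractional.
#'
#' @param col_centroid Kymograph column coordinate(s), 0-based, possibly
#'   fractional.
#' @param frame_rate Frames per second (> 0).
#' @return Arrival time(s) in seconds.
#' @examples
#' arrival_time(1438.7, 19.31) # 74.50 s
#' @export
arrival_time <- function(col_centroid, frame_rate) {
  check_scalar(frame_rate, "frame_rate", positive = TRUE)
  col_centroid / frame_rate
}
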