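#' Axial intensity profile of one frame
#'
#' Sums background-corrected counts over a transverse ROI (a set of rows)
#' for every column, giving intensity versus axial position. Column sums are
#' floored at 0; positions are `column * pixel_size_nm / 1000` um (0-based
#' columns).
#'
#' @param image Numeric matrix (one frame).
#' @param roi_rows 0-based row indices of the transverse ROI.
#' @param background_level Counts subtracted per pixel; default the frame
#'   median via [estimate_background()].
#' @param pixel_size_nm Pixel size in nm.
#' @param frame Frame index recorded in the output.
#' @return Tibble `frame, col, position_um, intensity`.
#' @export
axial_profile <- function(image, roi_rows, background_level = NULL,
                          pixel_size_nm = 267, frame = 0L) {
  if (!is.matrix(image)) abort("`image` must be a matrix.")
  if (length(roi_rows) == 0L) abort("`roi_rows` must not be empty.")
  if (any(roi_rows < 0L) || any(roi_rows >= nrow(image))) {
    abort("`roi_rows` must lie within the image (0-based).")
  }
  background_level <- background_level %||% estimate_background(image)$level
  sub <- image[roi_rows + 1L, , drop = FALSE] - background_level
  tibble(
    frame = as.integer(frame),
    col = seq_len(ncol(image)) - 1L,
    position_um = (seq_len(ncol(image)) - 1L) * pixel_size_nm / 1000,
    intensity = pmax(colSums(sub), 0)
  )
}

#' Fit a Gaussian to an axial intensity band
#'
#' Least-squares fit of `offset + amplitude * exp(-(x - mean)^2 / (2 sigma^2))`
#' to an axial profile, initialised from the profile's moments. The fit is
#' marked invalid (rather than raising) when it diverges: non-convergence,
#' non-positive amplitude, or sigma beyond the profile extent.
#'
#' @param profile Tibble from [axial_profile()] (needs `position_um`,
#'   `intensity`).
#' @return One-row tibble `frame, amplitude, mean_um, sigma_um, offset,
#'   valid`. `sigma_um` is the Gaussian sd; the half-width at half maximum
#'   is `1.1774 * sigma_um` (see [band_hwhm()]).
#' @export
fit_gaussian_band <- function(profile) {
  x <- profile$position_um
  y <- profile$intensity
  frame <- if ("frame" %in% names(profile) && nrow(profile)) profile$frame[1L] else 0L
  invalid <- tibble(frame = as.integer(frame), amplitude = NA_real_,
                    mean_um = NA_real_, sigma_um = NA_real_,
                    offset = NA_real_, valid = FALSE)
  if (sum(y > 0) < 5L) return(invalid)
  extent <- diff(range(x))
  w <- pmax(y - min(y), 0)
  if (sum(w) == 0) return(invalid)
  m0 <- sum(w * x) / sum(w)
  s0 <- sqrt(sum(w * (x - m0)^2) / sum(w))
  if (!is.finite(s0) || s0 <= 0) s0 <- extent / 10
  start <- list(offset = min(y), amplitude = max(y) - min(y), mean = m0, sigma = s0)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ offset + amplitude * exp(-(x - mean)^2 / (2 * sigma^2)),
      start = start,
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) return(invalid)
  p <- as.list(coef(fit))
  sigma <- abs(p$sigma)
  ok <- is.finite(p$amplitude) && p$amplitude > 0 &&
    is.finite(sigma) && sigma > 0 && sigma < extent
  if (!ok) return(invalid)
  tibble(frame = as.integer(frame), amplitude = p$amplitude, mean_um = p$mean,
         sigma_um = sigma, offset = p$offset, valid = TRUE)
}

#' Half-width at half maximum from a Gaussian sd
#'
#' The band "half-width" can be read as either the Gaussian sd or the HWHM;
#' fits store the sd (`sigma_um`) and this accessor converts to HWHM
#' (`1.1774 * sigma`).
#'
#' @param sigma_um Gaussian sd in um.
#' @export
band_hwhm <- function(sigma_um) sqrt(2 * log(2)) * sigma_um

#' Band stacking trace over a frame stack
#'
#' Fits a Gaussian band to the axial profile of every frame and summarises
#' the self-stacking dynamics: as the plug piles up at the gel interface the
#' fitted width narrows to a minimum while the mean position advances; after
#' stacking the band broadens again by diffusion and labeling heterogeneity.
#' Invalid per-frame fits are masked, not interpolated.
#'
#' @param stack A `frame_stack`, list of matrices, or single matrix.
#' @param roi_rows 0-based rows of the transverse ROI.
#' @param pixel_size_nm,frame_rate Acquisition metadata; default to the
#'   stack's camera when available.
#' @return A `stacking_trace`: list with `fits` (one row per frame, columns
#'   of [fit_gaussian_band()] plus `time_s`), `stacking_time_s` (time of the
#'   minimum valid sigma, earliest on ties) and `min_width_um` (that sigma).
#' @export
stacking_trace <- function(stack, roi_rows, pixel_size_nm = NULL,
                           frame_rate = NULL) {
  frames <- as_frame_list(stack)
  if (inherits(stack, "frame_stack")) {
    pixel_size_nm <- pixel_size_nm %||% stack$camera$pixel_size_nm
  }
  pixel_size_nm <- pixel_size_nm %||% 267
  frame_rate <- stack_frame_rate(stack, frame_rate)
  fits <- bind_rows(purrr::imap(frames, function(img, i) {
    prof <- axial_profile(img, roi_rows, pixel_size_nm = pixel_size_nm,
                          frame = i - 1L)
    fit_gaussian_band(prof)
  }))
  fits$time_s <- fits$frame / frame_rate
  valid <- fits[fits$valid, , drop = FALSE]
  if (nrow(valid) < 2L) {
    abort("Fewer than 2 frames produced a valid band fit.")
  }
  i_min <- which.min(valid$sigma_um)[1L]
  structure(
    list(fits = fits,
         stacking_time_s = valid$time_s[i_min],
         min_width_um = valid$sigma_um[i_min],
         frame_rate = frame_rate),
    class = "stacking_trace"
  )
}

#' @export
print.stacking_trace <- function(x, ...) {
  cat(sprintf(
    "<stacking_trace> %d frames (%d valid fits); min sigma %.3g um at t = %.3g s\n",
    nrow(x$fits), sum(x$fits$valid), x$min_width_um, x$stacking_time_s))
  invisible(x)
}

#' @rdname stacking_trace
#' @param x A `stacking_trace`.
#' @param ... Unused.
#' @export
tidy.stacking_trace <- function(x, ...) x$fits
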