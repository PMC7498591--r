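#' Gross molecular weight of a labeled protein
#'
#' Covalent dye conjugation adds a fixed mass increment per dye; at labeling
#' efficiency `efficiency` the expected number of conjugated dyes over
#' `n_sites` reactive residues is `efficiency * n_sites`, so the expected
#' gross mass is `bare_mass + efficiency * n_sites * delta_m`. For BSA
#' (66.4 kDa, 59 lysines) at 50% efficiency with Atto647N NHS-ester
#' (`delta_m = 0.6289` kDa) this gives 84.95 ~ 85 kDa.
#'
#' @param bare_mass Unlabeled protein mass in kDa.
#' @param n_sites Number of labelable residues (lysines for NHS-ester,
#'   cysteines for maleimide chemistry).
#' @param efficiency Labeling efficiency, a fraction in `[0, 1]`.
#' @param delta_m Mass added per conjugated dye in kDa (default 0.6289,
#'   Atto647N NHS-ester).
#' @return Expected labeled mass in kDa (vectorised over `bare_mass`,
#'   `n_sites`).
#' @examples
#' labeled_mass(66.4, 59, 0.5) # 84.95 kDa
#' @export
labeled_mass <- function(bare_mass, n_sites, efficiency, delta_m = 0.6289) {
  if (any(!is.finite(bare_mass)) || any(bare_mass < 0)) {
    abort("`bare_mass` must be non-negative.")
  }
  if (any(!is.finite(n_sites)) || any(n_sites < 0)) {
    abort("`n_sites` must be non-negative.")
  }
  check_fraction(efficiency, "efficiency")
  check_scalar(delta_m, "delta_m", nonneg = TRUE)
  bare_mass + efficiency * n_sites * delta_m
}

#' Electrophoretic mobility from migration time
#'
#' Mobility is drift velocity per unit field: the travel distance divided by
#' the migration time (taken relative to the free-dye front when `t_dye > 0`)
#' and by the field strength,
#' `mu = travel_distance / ((t_peak - t_dye) * field)`.
#'
#' @param travel_distance Distance from gel entrance to the observation
#'   point, in metres (the calibration runs here use 2.3 mm).
#' @param t_peak Band arrival time in seconds.
#' @param t_dye Free-dye front arrival time in seconds; 0 gives
#'   absolute-time mobility.
#' @param field Electric field strength in V/m.
#' @return Mobility in m^2/(V s); vectorised over `t_peak`.
#' @examples
#' mobility(2.3e-3, 114, 50.6, 12e3)
#' @export
mobility <- function(travel_distance, t_peak, t_dye = 0, field) {
  check_scalar(travel_distance, "travel_distance", positive = TRUE)
  check_scalar(field, "field", positive = TRUE)
  if (any(t_peak <= t_dye)) {
    abort("`t_peak` must exceed `t_dye` for every measurement.")
  }
  travel_distance / ((t_peak - t_dye) * field)
}

#' Fit the semi-log molecular-weight vs mobility calibration
#'
#' SDS-PAGE separations are conventionally summarised on a semi-log plot of
#' molecular weight against mobility; the relation is modelled as a decaying
#' exponential `MW = A * exp(-k * mu)`. The fit is linear least squares on
#' `log(MW) = log(A) - k * mu` (numerically stable and exact for noise-free
#' exponential data); the chi-squared of the exponential is also reported in
#' linear space (residual sum of squares of `MW - A exp(-k mu)`).
#'
#' @param mobilities Mobilities in m^2/(V s), all positive, length >= 3.
#' @param masses Labeled molecular weights in kDa, all positive, same length.
#' @param efficiency_assumed Labeling efficiency assumed when computing
#'   `masses` (stored for bookkeeping; the measured mobilities do not depend
#'   on it).
#' @param species Optional character vector of species names.
#' @return An object of class `mw_calibration` with elements `A_kda`, `k`,
#'   `r_squared`, `chi_squared`, `efficiency_assumed` and a `points` tibble.
#'   Supports [tidy()], [glance()], [predict_mass()] and [autoplot()].
#' @examples
#' mu <- c(4.36e-8, 1.04e-8, 6.1e-9, 3.02e-9)
#' fit_exponential(mu, 200 * exp(-5e8 * mu))
#' @export
fit_exponential <- function(mobilities, masses, efficiency_assumed = NA_real_,
                            species = NULL) {
  if (length(mobilities) != length(masses)) {
    abort("`mobilities` and `masses` must have equal length.")
  }
  if (length(masses) < 3L) {
    abort("Calibration requires at least 3 (mobility, mass) points.")
  }
  if (any(!is.finite(mobilities)) || any(mobilities <= 0) ||
      any(!is.finite(masses)) || any(masses <= 0)) {
    abort("Mobilities and masses must all be positive and finite.")
  }
  fit <- lm(log(masses) ~ mobilities)
  a <- exp(unname(coef(fit)[1L]))
  k <- -unname(coef(fit)[2L])
  tss <- sum((log(masses) - mean(log(masses)))^2)
  r2 <- if (tss > 0) 1 - sum(stats::resid(fit)^2) / tss else 1
  pred <- a * exp(-k * mobilities)
  out <- structure(
    list(
      A_kda = a,
      k = k,
      r_squared = r2,
      chi_squared = sum((masses - pred)^2),
      efficiency_assumed = efficiency_assumed,
      points = tibble(
        species = species %||% paste0("species_", seq_along(masses)),
        mobility = as.numeric(mobilities),
        mass_kda = as.numeric(masses),
        fitted_kda = pred
      )
    ),
    class = "mw_calibration"
  )
  out
}

#' Predict molecular weight from mobility
#'
#' Inverts the calibration `MW = A * exp(-k * mu)`; strictly decreasing in
#' mobility for `k > 0`.
#'
#' @param mobility Mobility in m^2/(V s); vectorised.
#' @param fit An `mw_calibration` from [fit_exponential()].
#' @return Predicted labeled molecular weight in kDa.
#' @export
predict_mass <- function(mobility, fit) {
  stopifnot(inherits(fit, "mw_calibration"))
  if (any(mobility < 0)) abort("`mobility` must be non-negative.")
  fit$A_kda * exp(-fit$k * mobility)
}

#' @export
print.mw_calibration <- function(x, ...) {
  cat("<mw_calibration>\n")
  cat(sprintf("  MW = %.4g kDa * exp(-%.4g * mu)\n", x$A_kda, x$k))
  cat(sprintf("  r^2 (log space) = %.4f, chi^2 (linear) = %.4g, n = %d\n",
              x$r_squared, x$chi_squared, nrow(x$points)))
  if (!is.na(x$efficiency_assumed)) {
    cat(sprintf("  assumed labeling efficiency = %.2f\n", x$efficiency_assumed))
  }
  invisible(x)
}

#' @rdname fit_exponential
#' @param x An `mw_calibration` object.
#' @param ... Unused.
#' @export
tidy.mw_calibration <- function(x, ...) {
  tibble(
    term = c("A_kda", "k"),
    estimate = c(x$A_kda, x$k)
  )
}

#' @rdname fit_exponential
#' @export
glance.mw_calibration <- function(x, ...) {
  tibble(
    A_kda = x$A_kda,
    k = x$k,
    r_squared = x$r_squared,
    chi_squared = x$chi_squared,
    efficiency_assumed = x$efficiency_assumed,
    n_points = nrow(x$points)
  )
}
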