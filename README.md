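# smsep

Single-molecule on-chip SDS-PAGE separation analysis in R.

## The problem

Bulk SDS-PAGE reads a gel lane as an ensemble band. When the same
separation is miniaturised into a shallow (~0.6 µm) gel-embedded
microfluidic channel and imaged with a single-photon-sensitive widefield
camera, every labeled protein is an individually resolvable
diffraction-limited spot, and a "gel lane" becomes a stream of arrival
events at video rate. That enables *digital* protein quantification —
counting molecules per mass band instead of integrating fluorescence — but
it requires a different analysis stack: per-frame spot detection and
subpixel localization, kymograph electropherograms, double-count-free
counting, single-molecule velocimetry, and a mobility-to-mass calibration.

`smsep` provides that stack for anyone analysing (or simulating) such
experiments: a ground-truthed synthetic video generator plus the complete
analysis chain, written tidyverse-style (tibbles in, tibbles out, `tidy()`
/ `glance()` for fitted objects, `autoplot()` for every result type).

## The core models

* **Transport.** Drift–diffusion per frame interval:
  `x <- x + v(x) dt + sqrt(2 D(x) dt) xi`, with `v = v_open` before the gel,
  `v = mu(m) E` inside it, and `v = mu(m) E s` (speed-up factor `s ~ 70`)
  after the gel exit. Drift is integrated piecewise across boundaries
  within each step, which is what makes plug stacking come out right: a
  200 µm plug entering at a 25-fold velocity drop compresses to
  `200/25 = 8` µm end-to-end.
* **Labeling.** Dyes bind each of `n` reactive residues independently with
  probability `f`; each adds `Δm = 0.6289` kDa, so the expected labeled
  mass is `m0 + f n Δm` (BSA: 66.4 kDa → ~85 kDa at `f = 0.5` over 59
  lysines). Zero-dye molecules are dark and invisible.
* **Mobility calibration.** `MW = A exp(-k mu)` with
  `mu = L / ((t_peak - t_dye) E)`, fitted as linear least squares in
  semi-log space; `predict_mass()` inverts it.
* **Detection.** Laplacian-of-Gaussian filtering, robust (MAD-based)
  thresholding, connected-component segmentation, response-weighted centre
  of gravity, background-corrected energy.

## Worked example

Simulate a four-species ladder (effective masses 17, 31, 46, 85 kDa at
full labeling) migrating through a scaled-down gel, image it, and recover
the mobility law:

```r
library(smsep)
library(dplyr)

species <- bind_rows(
  species_spec("LYS", 13.86, 5, 40),
  species_spec("CA",  24.71, 10, 40),
  species_spec("OA",  36.57, 15, 40),
  species_spec("BSA", 66.13, 30, 40)
)
channel <- channel_model(gel_start_um = 5, gel_end_um = 1000,
                         calib_A_kda = 200, calib_k = 2.8e9,
                         v_open_umps = 200, d_gel_um2ps = 0.5,
                         d_open_um2ps = 5, width_um = 24)
camera <- camera_model(frame_shape = c(96L, 480L))

sim <- simulate_trajectories(species, labeling_model(efficiency = 1),
                             channel, camera, duration_s = 36,
                             plug_length_um = 10, seed = 11)
stack <- render_video(sim, seed = 12)

kymo      <- build_kymograph(stack, column_index = 450L)
particles <- detect_particles(kymo$data)
ep        <- arrival_histogram(particles, camera$frame_rate, bin_width_s = 1)
(peaks    <- find_peaks(ep, min_separation_s = 2.5, min_height = 3))
#> # A tibble: 4 × 5
#>   time_s height n_particles left_s right_s
#>    <dbl>  <int>       <int>  <dbl>   <dbl>
#> 1   10.5     17          26      0      13
#> 2   14.5     18          28     13      17
#> 3   18.5     13          27     17      21
#> 4   30.5     10          37     21      35

travel_m <- (450 * 0.267 - channel$gel_start_um) * 1e-6
mu  <- mobility(travel_m, peaks$time_s, t_dye = 0, field = channel$field_vpm)
(fit <- fit_exponential(mu, masses = c(17, 31, 46, 85)))
#> <mw_calibration>
#>   MW = 190.4 kDa * exp(-2.681e+09 * mu)
#>   r^2 (log space) = 0.9963, chi^2 (linear) = 13.51, n = 4
predict_mass(mu, fit)
#> [1] 16.43210 32.29885 47.39850 81.91106
```

Four peaks appear in mass order (light first), each carrying its digital
per-peak molecule count (`n_particles`; 26 + 28 + 27 + 37 of the 160
simulated molecules reach the sampled column as resolvable detections).
The fitted pre-exponential and decay constant land within 5% of the
generative values (`A = 200` kDa, `k = 2.8e9`), and inverting the fit
returns each species' effective mass to within a few percent — the
single-molecule analogue of reading masses off a ladder lane.

`autoplot(kymo)`, `autoplot(ep)` and `autoplot(fit)` draw the kymograph,
the electropherogram and the semi-log calibration; `tidy(fit)` and
`glance(fit)` return the fit as tibbles.

## Package layout

| Area | Functions |
| --- | --- |
| Synthetic data | `species_spec()`, `labeling_model()`, `channel_model()`, `camera_model()`, `sample_labeling()`, `simulate_trajectories()`, `render_video()`, `write_dataset()`, `read_dataset()` |
| Detection | `detection_params()`, `estimate_background()`, `detect_particles()`, `detect_stack()` |
| Kymographs | `build_kymograph()`, `fraction_above_threshold()`, `arrival_time()` |
| Band dynamics | `axial_profile()`, `fit_gaussian_band()`, `stacking_trace()`, `band_hwhm()` |
| Quantification | `arrival_histogram()`, `count_frame_stack()`, `find_peaks()`, `intensity_histograms()` |
| Tracking | `link_particles()`, `track_velocity()`, `track_velocities()`, `velocity_populations()` |
| Calibration | `labeled_mass()`, `mobility()`, `fit_exponential()`, `predict_mass()` |
| Pipeline | `validate_config()`, `run_pipeline()` |

See the vignette (`vignettes/single-molecule-separation.Rmd`) for the
models, assumptions, parameter choices and known limitations.
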