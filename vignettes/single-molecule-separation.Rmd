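---
title: "Single-molecule on-chip SDS-PAGE: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-molecule on-chip SDS-PAGE: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smsep)
```

## The measurement this package models

In on-chip single-molecule SDS-PAGE, SDS-denatured and fluorescently labeled
proteins are injected as a short plug into a shallow (sub-micron)
microfluidic channel containing a UV-polymerised polyacrylamide gel, and
driven electrophoretically. The gel slows migration in a mass-dependent way,
so an injected mixture separates into bands; the shallow channel keeps every
molecule in focus, so a widefield EMCCD records each protein as a
diffraction-limited spot at video rate (here 19.31 frames/s at ~267 nm/px).
Analysis then proceeds molecule by molecule: spots are detected and
localized per frame, arrival times at a fixed position are histogrammed into
an electropherogram, bands are counted digitally, and peak migration times
are converted to electrophoretic mobilities and calibrated against molecular
weight.

`smsep` implements the full chain twice over: a ground-truthed *simulator*
of such videos, and the *analysis* that consumes them (real or simulated).
The simulator is first-class, tested code: every analysis claim in the test
suite is checked against the generative truth.

## Transport model

The channel is one axis (`x`, in µm, mapped to image columns); transverse
position maps to rows. Three regions govern the drift velocity:

* **open channel** (`x < gel_start`): constant plug velocity `v_open`;
* **gel** (`gel_start <= x < gel_end`): `v(m) = mu(m) * E`, with the
  mobility law `mu(m) = (ln A - ln m) / k` — the inverse of the calibration
  `m = A exp(-k mu)` that the analysis end fits;
* **post-gel** (`x >= gel_end`): the in-gel velocity times
  `post_gel_speedup` (default 70), modelling ejection into the
  low-resistance open channel.

Motion integrates per frame interval (`dt = 1/frame_rate`) by
Euler–Maruyama: `x <- x + v(x) dt + sqrt(2 D(x) dt) xi`. One refinement
matters: the *drift* part of a step is integrated piecewise-analytically
across region boundaries. A molecule reaching the gel interface mid-step
continues at the gel speed for the remainder of that step, rather than
overshooting at the open-channel speed. Without this, a plug entering at
`v_open/v_gel = 25` would smear by up to `v_open * dt` (~5 µm at defaults)
per molecule and the kinematic stacking prediction — a 200 µm plug
compresses to `200/25 = 8` µm end-to-end — could not be reproduced at any
useful tolerance. Diffusion is still applied once per step; per-frame
displacements are far smaller than any region, so no further sub-stepping
is used.

Stacking therefore emerges kinematically (first-in molecules crawl while
late ones catch up), not electrochemically: no glycine/Tris front, Joule
heating or current-leakage physics is modelled, matching a device that has
no stacking gel in the first place.

## Labeling model

Each protein species has a bare mass and a number of labelable residues
(lysines for NHS-ester, cysteines for maleimide chemistry). Each residue is
conjugated independently with probability `efficiency`; each dye adds
`delta_m = 0.6289` kDa. The expected labeled mass is
`bare + efficiency * n_sites * delta_m` — for BSA (66.4 kDa, 59 lysines) at
50% efficiency, `labeled_mass(66.4, 59, 0.5)` gives
`r round(labeled_mass(66.4, 59, 0.5), 2)` kDa, i.e. ~85 kDa. Molecules that
draw zero dyes are *dark*: they are simulated but never rendered (unlabeled
protein is invisible), and are retained in an audit table. Labeling
heterogeneity is the dominant source of band broadening at long migration
times; the charge added by dyes is *not* modelled — the calibration is
mass-only.

## Camera model

Spots render as pixel-integrated isotropic Gaussians (sd `psf_sigma_px`,
default 1.1 px ≈ 294 nm — a diffraction-limited spot at NA 1.45 and ~670 nm
emission, sampled at 267 nm) with expected photons
`n_dyes * photons_per_dye`. Pixel values are
`baseline + em_gain * Poisson(photons) + Normal(0, read_noise_sd)`, clipped
to 16 bits. Two simplifications: EM-gain excess noise is folded into
`read_noise_sd` rather than modelled as a gamma cascade (none of the
analysis depends on the exact noise law), and motion blur within a frame is
omitted (exposure is short relative to in-gel transit). The field of view
can be positioned along the channel via `fov_origin_um`, mirroring imaging
a ~137 µm window 1.3–2.3 mm into a much longer gel.

## Detection

Frames (or kymographs) are filtered with a zero-sum Laplacian-of-Gaussian
kernel; the negated response is positive over bright blobs. Pixels above
`k_threshold` (default 5) robust standard deviations (1.4826 × MAD) of the
response are segmented into connected components (8-connectivity, minimum
area 2 px to reject hot pixels). Per segment, the position is the
response-weighted centre of gravity — response weights are stable under
slowly varying background — while the *energy* is the sum of
background-corrected raw counts, background being the frame median. The
LoG scale defaults to 1.5 px, following the `sigma * sqrt(2)` blob-matching
heuristic for a 1.1 px PSF. Touching spots are deliberately not split by
watershed: the device is designed for low occupancy, and a merged segment
counts as one molecule. "Energy" could also be read as (summed value) ×
(area); summed background-corrected counts is used, with area reported
separately.

All reported coordinates are 0-based subpixel values: position in µm is
`col * pixel_size/1000`, time in seconds is `frame/frame_rate` (and
`col/frame_rate` on a kymograph). Fractional centroids are never rounded
before conversion.

## Kymographs, electropherograms and digital counting

A kymograph concatenates one fixed pixel column (conventionally the central
column, 256) of every frame. Construction is lossless; the percentile
stretch seen in `autoplot()` is display-only and no quantitative operation
ever consumes rescaled values. Whether the original experiments averaged a
few columns is unknowable from the description; exactly one column is used,
as written. The normalized trace is the fraction of pixels in each time
column above a threshold, defaulting to background + 5 robust sds.

Arrival histograms bin detection times (default 5 s bins) relative to a
reference — conventionally the free-dye front, so `t = 0` marks the fastest
population; pre-reference times go to an underflow count and the reference
is stored so absolute times remain recoverable. Peak finding takes local
maxima above a height floor, merges peaks closer than a separation (taller
wins, earlier on ties), delimits each peak at the enclosing minima, and sums
counts per region so that peaks tile the histogram: per-peak digital counts
add up to the total.

Counting over full frame stacks avoids double counting with a stripe rule:
a stripe of width `floor(drift)` px is watched every frame, and a detection
is accepted only in the frame it first enters. Choices worth recording:
the stripe rule was chosen over frame-skipping (either reading is
consistent with "non-overlapping regions in successive frames"); the
duplicate-suppression radius defaults to 0.5 px, about twice the per-frame
diffusive jitter of a gel-embedded molecule, so it suppresses lingerers
without rejecting distinct neighbours; a molecule that re-enters the stripe
(reflected trajectory) is counted twice, inherently; and a fractional drift
(e.g. 4.65 px/frame through a 4 px stripe) lets molecules jump the stripe
between frames, undercounting by roughly the fractional part — drift
estimates should be near-integer in pixels where possible.

## Band dynamics

Axial profiles sum background-corrected counts over a transverse ROI (the
ROI is a required user choice; it is not inferable from data). Each frame's
profile is fitted with `offset + A exp(-(x-m)^2/(2 sigma^2))` by
Levenberg–Marquardt least squares, initialised from profile moments;
divergent fits (non-convergence, `A <= 0`, sigma beyond the profile extent)
are flagged invalid and masked, never interpolated. Every frame is fitted,
not a few representative ones. "Half-width" is ambiguous between the
Gaussian sd and the HWHM; `sigma_um` is stored and `band_hwhm()` converts
(HWHM = 1.1774 sigma). The stacking summary reports the time of minimum
valid sigma (earliest on ties); note that the fit can lock onto the sharp
stacked spike slightly before the plug tail has fully entered, so the
minimum marks band formation, not exactly full entry.

## Tracking and gel-exit statistics

Linking is greedy nearest-neighbour per frame transition, assignments made
in order of ascending distance within `max_disp_px` (sensible default: 3×
the expected per-frame drift); one missed frame is bridged by extrapolating
the last displacement. Track velocity is the least-squares slope of axial
position against time, requiring at least 3 points. For gel-exit analysis
the boundary column is supplied by the user (it is marked manually on real
images); each track splits into an in-gel segment (points at or before the
boundary) and a post-gel segment, the straddling displacement belonging to
neither, and the two pooled populations give means, sds, sems and their
fold change.

## Calibration

Mobility is operationally `mu = L / ((t_peak - t_dye) * E)`, migration time
taken relative to the free-dye front (subtraction, consistent with the
`t = 0` convention above). The molecular-weight relation `m = A exp(-k mu)`
is fitted as linear least squares on `ln m = ln A - k mu` — numerically
stable and exact on noise-free data — with the chi-squared of the
exponential also reported in linear space. `predict_mass()` inverts the
fit; it is strictly decreasing in mobility. Because true labeling
efficiencies are unknown in practice, the fit stores the efficiency assumed
when computing labeled masses; sweeping it rescales masses but never
reorders mobilities.

## What the simulator does and does not establish

The generator reproduces: plug injection and kinematic stacking,
mass-dependent migration with binomial labeling heterogeneity, gel-exit
acceleration, diffraction-limited PSFs, and shot/read noise on a 16-bit
EMCCD. It does not reproduce: non-specific surface adsorption (a small
minority population in real data), intra-frame motion blur, EM-gain excess
noise statistics, electrochemical stacking, field non-uniformities, or
charge effects of labeling. Tests passing on simulated data therefore
validate the *algorithms* under known truth — recall/precision and
localization of the detector, digital-count accuracy, velocity and
calibration recovery — not the fidelity of any particular laboratory
dataset.

The plug's initial concentration profile is taken uniform (nothing in the
physical description constrains it), and the open-channel diffusivity is a
free parameter of the generator; defaults (`D_gel` 0.2 µm²/s, `D_open`
20 µm²/s) are plausible for a ~30–85 kDa SDS-denatured protein strongly
restricted by an 8% gel versus nearly free in the open channel.

## Problem sizes used by the test suite

Tests run on scaled-down geometries chosen so the full chain is exercised
in seconds: ladders of four species (effective masses 17/31/46/85 kDa at
full labeling) migrating tens of µm through a 96 × 480 px field rather than
millimetres through 512 × 512, 40–500 molecules per run, and mobility laws
rescaled so in-gel velocities span ~4–20 µm/s. The quantities checked —
compression ratios, recall/precision, count accuracy, recovered `(A, k)` —
are dimensionless or relative, so the scaling leaves their interpretation
unchanged. One documented caveat: species generated at mean arrival times
55 and 60 s with sd 3 s are closer than twice their sd, so their mixture
density is mathematically unimodal and no binned peak finder can resolve
them as two peaks; the corresponding check documents this limit rather than
a detector defect.

## Known limitations

* Merged (touching) spots count as one molecule by design; at occupancies
  far above the device's design regime counts will be biased low.
* The stripe counter's undercount grows with the fractional part of the
  per-frame drift.
* Greedy linking can swap identities when distinct molecules approach
  within the per-frame displacement scale.
* The calibration is mass-only; systematic charge shifts from labeling
  would appear as mass biases.
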