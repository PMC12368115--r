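---
title: "Double-helix PSF localisation: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Double-helix PSF localisation: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(helixloc)
```

## The problem and the approach

A double-helix point spread function (DH-PSF) microscope images each point
emitter as two lateral lobes whose common orientation rotates with the
emitter's axial position, encoding z over a roughly 4 µm depth of field.
Recovering 3D positions from such movies has two halves:

1. **2D**: find and fit every lobe in every frame (any sub-pixel spot fitter
   will do; `helixloc` ships one and also reads tables from an external
   fitter).
2. **3D**: decide which two lobes belong to the same molecule, convert the
   pair's rotation angle into z, and reject ambiguous pairs.

`helixloc` solves the second half the way the fastest analytical DH-PSF
pipelines do: per frame, the pairwise Euclidean distance matrix of the lobe
centres is computed, and lobe pairs whose separation falls inside an expected
interlobe-distance window become pairing candidates. Conflicts are resolved
greedily — candidates are processed in ascending deviation of their distance
from the window midpoint, and a pair is accepted only if neither lobe is
already used — which is deterministic and fast, at the cost of occasionally
missing a globally optimal assignment (the test suite measures the greedy
versus maximum-matching agreement instead of assuming it). Each accepted pair
yields a localisation: x and y from the lobe midpoint corrected by the
z-dependent lateral *wobble* of the PSF, z from the rotation angle via the
calibration, and a total intensity from the summed lobe fluxes. Pairs whose
interlobe distance or lobe intensity ratio deviates from the calibration's
expectation at that angle, or whose angle lies outside the calibrated range,
are flagged and excluded from exports.

## Calibration model

A calibration series images one fluorescent bead stepped through known axial
positions (the common scheme is 119 positions 33.3 nm apart, spanning
~3.93 µm). For every frame the two lobes give five quantities as functions of
the rotation angle θ ∈ [0°, 180°): the known z, the midpoint shift (dx, dy)
relative to the first usable frame (the wobble), the interlobe distance d,
and the intensity ratio r. Each is fitted with a degree-15 polynomial by
least squares.

Numerically the fit uses a Chebyshev basis on θ rescaled to [−1, 1], solved
by QR; a raw monomial basis of degree 15 over tens of degrees is
catastrophically ill-conditioned. The degree is a parameter (`degree`,
sensible range 3–15): 15 tracks a clean bead series essentially exactly,
while noisy series benefit from 8–12. Spline calibration is deliberately out
of scope — the polynomial is more robust when either the calibration or the
data is noisy, which is the regime this package targets.

Because θ is a line orientation it folds at 180°, and a calibration series
covering more than half a turn makes θ → z ambiguous. A fold shows up as a
near-180° jump of the folded angle between consecutive frames and
`build_calibration()` refuses such series, pointing to `frame_range`.
Strict frame-to-frame monotonicity is *not* required: at realistic noise the
1.4°-per-frame rotation step is comparable to the angle jitter, so strict
monotonicity would reject valid data. `calibration_diagnostics()` reports
the strict flag, the per-curve residual RMS, and a suggested trimmed angle
range (frames whose z residual exceeds 3× the median absolute residual are
peeled off both ends).

Two conventions are fixed package-wide and must agree between calibration,
unmixing and simulation:

* **Coordinates**: 0-based pixel indices, x = column, y = row, a peak at the
  centre of pixel (i, j) has `x_px = j`, `y_px = i`; physical position is
  coordinate × pixel size. The pixel size is user metadata (typically
  measured with a grating target), never read from TIFF tags.
* **Ratio ordering**: the intensity ratio is the lobe with smaller x (ties:
  smaller y) over the other lobe. Any fixed rule works as long as it is
  applied everywhere; near θ = 90° the smaller-x identity swaps between the
  physical lobes, which is why the simulator assigns fluxes by the same rule
  rather than to a fixed physical lobe.

## The simulator

`simulate_calibration()` and `simulate_dataset()` implement a parametric
rotating two-lobe PSF: each lobe is a pixel-integrated 2D Gaussian; the angle
law is linear in z (θ₀ = 5°, span 170° < 180°); the interlobe distance grows
quadratically, d(z) = d₀ + d₂z² with d₀ = 1050 nm and +25 % at the range
extremes; the intensity ratio is linear, r(z) = 1 + 1.25·10⁻⁴ z (0.75–1.25
over the range); and the midpoint wobbles sinusoidally with amplitudes
(40, 30) nm, zero at the bottom of the range so the first calibration frame
is the natural wobble reference. Defaults mimic a commercial DH-PSF system:
210 nm pixels, lobe σ = 1.1 px, z ∈ (−2000, 2000) nm.

Benchmark scenes place `per_frame` molecules uniformly (sub-pixel) over a
256 × 256 px canvas — a typical field-of-view crop of a 512 × 512 EMCCD —
with a border margin that keeps whole PSFs inside the frame, z uniform over
the range, and per-molecule intensity factors drawn from U(1, 1.2). Noise is
i.i.d. Gaussian per pixel on a constant background of mean level 50; the
noise sd is solved from the requested signal-to-noise ratio, defined as the
mean brightest rendered pixel across molecules divided by the noise sd.
Stacks stay floating-point in memory (at S/N 5.8 the noise sd is ~59 counts
on a background of 50, and forcing unsigned integers would clip ~20 % of
pixels at zero); quantisation to 16-bit counts happens only when writing
TIFF.

What the simulator deliberately does **not** model: vectorial diffraction or
phase-retrieved PSF shapes (real DH-PSF lobes deform and exchange energy
with defocus), Poisson shot noise and EMCCD excess noise, sCMOS
pixel-dependent noise, aberrations, and molecules denser than one well-
separated pair per PSF footprint. Consequently the benchmark results below
say that the *pairing-and-calibration machinery* is correct and robust to
Gaussian background noise and crowding — they do not promise the same
Jaccard index on a real microscope, where detection quality and PSF model
mismatch dominate.

## Spot detection

Candidates are local maxima of the Gaussian-smoothed frame (σ = expected
lobe σ, a matched filter) above the smoothed frame's median plus
`threshold` × its robust noise sd (1.4826 × MAD); maxima closer than
`min_separation_px` keep only the brighter. Each candidate is fitted as a
pixel-integrated symmetric 2D Gaussian (centre, flux, width, constant
offset) by Levenberg–Marquardt with an analytic Jacobian on a
`fit_window_px` × `fit_window_px` window. Pixels of the window lying closer
to another candidate are excluded (a Voronoi mask): without this, the
partner lobe of the same molecule — only ~5 px away — biases the fit enough
to lose the diagonal orientations entirely. Fits are rejected for
non-convergence, vanishing amplitude, width outside [0.5, 3] × the prior, a
centre drifting out of the window, or a clipped border window; fits landing
within 1 px of an accepted brighter fit are dropped as duplicates.

## Filter tolerances

The distance and ratio filters are *relative to the calibration*:
reject when |d_obs − d(θ)| > `tol_d`·d(θ), or when
|log r_obs − log r(θ)| > log(1 + `tol_r`) (log scale so r and 1/r deviate
symmetrically). Both default to 0.25, a sensible gate for high-S/N data.

The benchmark configuration relaxes the ratio tolerance to `tol_r = 2`. The
reason is photometric: the scatter of the log flux ratio of a fitted lobe
pair is ~0.30 at S/N 5.8 (~0.12 at S/N 23), so log(1.25) ≈ 0.22 would gate
at below one sigma and reject ~40 % of perfectly good pairs at low S/N,
while log(3) ≈ 1.1 sits near 3.7 sigma. Measured on the simulator, relaxing
the ratio gate changes precision by under half a point (wrong pairings are
mostly caught by the pairing-distance window and the distance filter) while
restoring the lost sensitivity. The same logic applies to real data: gate
ratios at ~3 sigma of your photometric scatter, and keep the stringent
default only for bright samples.

The pairing window defaults to [0.8 × min d(θ), 1.2 × max d(θ)] derived from
the calibration, rather than hard-coded limits, so PSFs whose lobes separate
strongly at the range extremes remain pairable.

## Evaluation conventions

Matching is greedy one-to-one within each frame by ascending 3D distance
among candidates within `tol_xy_nm` (250) and `tol_z_nm` (500); the radii
have no universal convention, so they are explicit arguments recorded in
every report. Precision, sensitivity and the Jaccard index
TP/(TP+FP+FN) follow the SMLM-challenge definitions.

Restricted-range ("optimal z-range") metrics match on the full tables first
and then count within the window: TP are matches whose truth is inside, FN
unmatched in-window truths, FP unmatched in-window detections. Filtering
detections by estimated z *before* matching would flip molecules localised
within their axial error of the window boundary into simultaneous FP+FN,
which measurably distorts the counts (at S/N 6.6 roughly two thirds of the
apparent false positives were such boundary flips).

`eligibility_filters()` applies the border and dimmest-fraction exclusions
jointly — both criteria are evaluated on the supplied table and intersected
— so the survivor set does not depend on the order the criteria are listed.

## Post-processing

* **Drift**: frames are tiled into blocks, each block's localisations are
  rendered into a 2D histogram, and block shifts relative to the first block
  are read off the FFT cross-correlation peak with parabolic sub-bin
  refinement; per-frame shifts are linearly interpolated between block
  midpoints. Only lateral drift is corrected. The first block is the
  reference by common convention. A fiducial-track mode subtracts the
  fiducial's per-frame displacement from its mean instead.
* **Blinking grouping** links localisations closer than `dxy_max_nm`
  laterally (and `dz_max_nm` axially, if set) within `max_gap_frames`, and
  merges each *connected component* (transitive closure — the natural
  reading when a molecule blinks across many frames) into one row with
  unweighted mean coordinates, summed intensity and a multiplicity count.
  Chained linking can walk beyond `dxy_max_nm`; `max_extent_nm` warns when
  it does. Intensity weighting of the mean is deliberately not applied.
* **FSC**: the kept localisations are randomly split in half (seeded),
  voxelised (default 5 nm), blurred with a 3D Gaussian (σ = (3, 3, 5)
  voxels, interpreted as sigmas matching the expected 3D localisation
  precision), and correlated per spherical shell one frequency bin wide on
  the zero-padded cube; the resolution is read where the curve first
  descends through 1/7 (linearly interpolated between shells). An identical
  positive real-space filter cancels exactly in the correlation, so the
  blur does not change the FSC value; it is applied for fidelity with the
  standard pipeline. If the curve never crosses the threshold the
  resolution is reported as twice the voxel (the Nyquist limit of the
  grid). A block-wise variant analyses 1 µm cubes holding more than 1,000
  localisations and reports the per-block map and mean.

## Numerical choices and degenerate inputs

* Ties in pairing and matching break on row indices, making every pipeline
  stage deterministic given identical inputs; simulation randomness is
  controlled by explicit seeds.
* Flat fit windows converge to zero amplitude and are rejected rather than
  returned; coincident peaks (zero interlobe distance) are an error.
* Zero-denominator metrics (empty truth or detection sets) return `NA` with
  an `"undefined"` attribute instead of crashing or silently printing 0.
* Angles are folded with `%%` into [0, 180); model evaluation outside the
  calibrated angle range returns `NA` plus an `in_range` flag, and callers
  treat those as exclusions, never extrapolations.
* Chebyshev evaluation uses the three-term recurrence, so diagnostics can
  evaluate marginally outside [−1, 1] without NaNs.

## Benchmark problem sizes

The package's acceptance analogues of the published benchmarks run the full
pipeline (simulate → detect → unmix → evaluate against truth) on 500-frame
scenes at S/N 5.8–23 and 5–15 molecules per frame, and a 300-frame-per-cell
grid over S/N {5.8, 6.6, 23} × density {5, 10, 15} for the full-range
worst case; the published experiments used 5,000-frame stacks of the same
densities. These sizes keep a full run on one CPU core in minutes while the
Jaccard estimates retain sampling errors well below the margins being
tested (several thousand molecules per condition).

## Known limitations

* The Gaussian-pair PSF is an approximation; on real data the detection
  stage (or an external fitter) and the calibration absorb the difference,
  but simulation-based numbers transfer only qualitatively.
* Greedy pairing can mis-pair in crowded frames where a wrong pair's
  distance happens to sit closer to the window midpoint than the true
  pairs'; the filters catch only part of these.
* Rotation angles beyond the calibrated range — including any physical
  rotation past 180° — are unrecoverable by design and are excluded, not
  guessed.
* No axial drift correction, no multi-emitter unmixing of overlapping
  PSFs, no field-dependent aberration modelling.
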