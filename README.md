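# helixloc

3D single-molecule localisation microscopy with the double-helix point
spread function (DH-PSF), for microscopists and image analysts who have
per-frame 2D spot detections (or raw TIFF stacks) and need 3D coordinates.

A DH-PSF microscope images each emitter as two lobes that rotate about
their midpoint as the emitter moves axially: the rotation angle θ of the
lobe pair encodes z over a ~4 µm range. `helixloc` turns lobe detections
into 3D localisations by

1. **pairing** the lobes of each frame through the pairwise Euclidean
   distance matrix — lobe pairs whose separation d lies in an expected
   window are paired greedily by closeness to the window midpoint;
2. **calibrating** θ → z with degree-15 polynomial fits (Chebyshev basis)
   of z, midpoint wobble (dx, dy), interlobe distance d, and lobe
   intensity ratio r against θ, from a bead z-stack (e.g. 119 steps of
   33.3 nm);
3. **localising**: x, y = lobe midpoint − wobble(θ), z = z(θ),
   intensity = summed lobe flux;
4. **filtering**: pairs with θ outside the calibrated range, or with
   |d_obs − d(θ)| > tol_d·d(θ), or |log r_obs − log r(θ)| > log(1+tol_r),
   are rejected.

Around that core the package provides a spot detector (matched-filter
candidates + pixel-integrated 2D Gaussian fits), a parametric two-lobe PSF
simulator with exact ground truth, benchmarking (precision, sensitivity,
Jaccard index TP/(TP+FP+FN), localisation accuracy, sensitivity-vs-z),
lateral drift correction, blinking grouping, Fourier shell correlation
resolution (1/7 threshold), and readers/writers for TIFF stacks, peak and
localisation CSVs, ViSP export and JSON calibration models.

## Worked example

Simulate a calibration stack and a benchmark scene, run the full pipeline,
and score it against the known ground truth:

```r
library(helixloc)

gen <- dh_generator()                      # 210 nm pixels, ~4 um z range
cal <- simulate_calibration(gen)           # 119 bead frames, 33.3 nm steps
cal_peaks <- detect_stack(cal$stack)
model <- build_calibration(cal_peaks, z_step_nm = 33.3,
                           pixel_size_nm = 210, z_offset_nm = -2000)
model
#> <dh_calibration>
#>   degree 15, 119 frames, angle range [5.00, 172.00] deg
#>   pixel 210 nm, z step 33.3 nm, z offset -2000 nm
#>   residual RMS: z 0.122 nm, d 0.203 nm, ratio 0.0021, dx 0.14 nm, dy 0.15 nm

sim <- simulate_dataset(gen, n_frames = 100, per_frame = 10,
                        snr_target = 6.6, seed = 42)
peaks <- detect_stack(sim$stack)
locs  <- unmix_stack(peaks, model, unmix_params(model, tol_r = 2))

report <- match_localisations(locs, sim$scene$truth,
                              tol_xy_nm = 250, tol_z_nm = 500)
report
#> <dh_match> TP 965, FP 4, FN 35 (tol xy 250 nm, z 500 nm)
#>   precision 0.996, sensitivity 0.965, Jaccard 0.961
accuracy_stats(report)$summary
#> # A tibble: 1 × 3
#>   median_d_xy_nm median_abs_d_z_nm median_d_3d_nm
#>            <dbl>             <dbl>          <dbl>
#> 1           22.0              28.3           40.9
```

The calibration closes on the simulator to ~0.1 nm; at signal-to-noise 6.6
(mean brightest pixel / noise sd) with 10 molecules per 256×256 px frame
the pipeline recovers 96.5 % of molecules with 0.4 % false positives and a
median 3D error of ~41 nm. `autoplot(model)` shows the five calibration
curves, `write_visp(locs, "locs.3d")` exports kept localisations for ViSP,
and `tidy()`/`glance()` give broom-style summaries of models and reports.

A command-line front end wrapping the same functions ships in
`inst/exec/helixloc` (subcommands `simulate`, `detect`, `calibrate`,
`unmix`, `evaluate`, `drift`, `group`, `fsc`).

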