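# Scaled-down analogues of the published benchmark conditions, shared by the
# acceptance tests. Each scene runs the full pipeline (simulate -> detect ->
# unmix) once and is cached for the whole test run.

# restricted axial window: the central 80 % of the axial range, inside which
# all compared algorithms operate validly
restricted_window <- function() c(-1600, 1600)

run_benchmark_scene <- function(n_frames, per_frame, snr, seed) {
  gen <- fix_generator()
  model <- fix_model()
  sim <- simulate_dataset(gen, n_frames = n_frames, per_frame = per_frame,
                          snr_target = snr, seed = seed)
  peaks <- detect_stack(sim$stack, detection_params())
  locs <- unmix_stack(peaks, model, benchmark_params(model))
  list(locs = locs, truth = sim$scene$truth)
}

bench_metrics <- function(scene, z_window = NULL) {
  loc_metrics(match_localisations(scene$locs, scene$truth,
                                  tol_xy_nm = 250, tol_z_nm = 500,
                                  z_window_nm = z_window))
}

# hardest published condition: lowest S/N, highest density
fix_bench_hard <- function() {
  fixture("bench_hard", function() run_benchmark_scene(500, 15, 5.8, 19))
}

# high-S/N condition
fix_bench_snr23 <- function() {
  fixture("bench_snr23", function() run_benchmark_scene(500, 10, 23, 29))
}

# intermediate S/N on the default (Microscope-1-like) geometry; shared by
# the restricted-range and full-range acceptance checks
fix_bench_mid <- function() {
  fixture("bench_mid", function() run_benchmark_scene(500, 10, 6.6, 37))
}
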