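# Shared fixtures, computed once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# default generator: the study conditions of the benchmark simulations
fix_generator <- function() fixture("gen", function() dh_generator())

# a small-canvas generator for cheap scenes
fix_generator_small <- function() {
  fixture("gen_small", function() dh_generator(canvas_px = c(64, 64)))
}

# calibration model from a noiseless simulated bead stack (119 x 33.3 nm),
# built through the real detection path
fix_model <- function() {
  fixture("model", function() {
    gen <- fix_generator()
    cal <- simulate_calibration(gen)
    peaks <- detect_stack(cal$stack, detection_params())
    build_calibration(peaks, z_step_nm = 33.3, degree = 15,
                      pixel_size_nm = gen$pixel_size_nm,
                      z_offset_nm = gen$z_range_nm[1])
  })
}

fix_calibration_peaks <- function() {
  fixture("cal_peaks", function() {
    gen <- fix_generator()
    cal <- simulate_calibration(gen)
    list(peaks = detect_stack(cal$stack, detection_params()), z_nm = cal$z_nm)
  })
}

# small noisy scene at high S/N under the study field of view
fix_scene_snr23 <- function() {
  fixture("scene23", function() {
    gen <- fix_generator()
    simulate_dataset(gen, n_frames = 12, per_frame = 5, snr_target = 23, seed = 424)
  })
}

# the benchmark filter configuration (see the methods vignette): distance
# tolerance at the default, ratio tolerance opened up to ~3.7 sigma of the
# photometric scatter at the lowest benchmarked S/N
benchmark_params <- function(model) unmix_params(model, tol_d = 0.25, tol_r = 2)

# --- independent oracles -------------------------------------------------

# optimal one-to-one matching TP count: maximum-cardinality bipartite
# matching over the tolerance-feasible pairs (igraph as independent oracle)
oracle_optimal_tp <- function(detected, truth, tol_xy_nm, tol_z_nm) {
  nd <- nrow(detected); nt <- nrow(truth)
  edges <- integer(0)
  for (i in seq_len(nd)) {
    dxy <- sqrt((truth$x_nm - detected$x_nm[i])^2 + (truth$y_nm - detected$y_nm[i])^2)
    dz <- abs(truth$z_nm - detected$z_nm[i])
    for (j in which(dxy <= tol_xy_nm & dz <= tol_z_nm)) {
      edges <- c(edges, i, nd + j)
    }
  }
  if (length(edges) == 0L) return(0L)
  g <- igraph::make_bipartite_graph(c(rep(FALSE, nd), rep(TRUE, nt)),
                                    edges = edges)
  igraph::max_bipartite_match(g)$matching_size
}

# brute-force connected components under a pairwise link predicate
oracle_components <- function(n, linked) {
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      if (linked(i, j) && comp[i] != comp[j]) {
        old <- max(comp[i], comp[j]); new <- min(comp[i], comp[j])
        comp[comp == old] <- new
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  match(comp, unique(comp))
}

# brute-force maximal pairing count for pair_peaks instances (one shared
# peak set; n <= 6): maximum matching by recursion
oracle_max_pairs <- function(dm, d_min, d_max) {
  n <- nrow(dm)
  pairs <- which(upper.tri(dm) & dm >= d_min & dm <= d_max, arr.ind = TRUE)
  best <- 0L
  rec <- function(used, k, count) {
    best <<- max(best, count)
    if (k > nrow(pairs)) return()
    for (m in k:nrow(pairs)) {
      i <- pairs[m, 1]; j <- pairs[m, 2]
      if (!used[i] && !used[j]) {
        u <- used; u[c(i, j)] <- TRUE
        rec(u, m + 1L, count + 1L)
      }
    }
  }
  if (nrow(pairs) > 0) rec(logical(n), 1L, 0L)
  best
}
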