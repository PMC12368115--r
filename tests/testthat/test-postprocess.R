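# Drift correction, blinking grouping and Fourier shell correlation.

# localisations of a fixed structure re-sampled over frames: blinking sites
# plus localisation jitter, so different frame blocks share the structure
# that cross-correlation locks onto
drift_cloud <- function(n = 400, seed = 5, n_sites = 50) {
  set.seed(seed)
  sx <- runif(n_sites, 0, 6000); sy <- runif(n_sites, 0, 6000)
  site <- sample(n_sites, n, replace = TRUE)
  tibble::tibble(
    frame = sort(sample(0:199, n, replace = TRUE)),
    x_nm = sx[site] + rnorm(n, 0, 10), y_nm = sy[site] + rnorm(n, 0, 10),
    z_nm = runif(n, -500, 500), intensity = 100
  )
}

test_that("cross-correlation recovers a block translation within a quarter bin", {
  base <- drift_cloud()
  shifted <- base
  second <- shifted$frame >= 100
  shifted$x_nm[second] <- shifted$x_nm[second] + 100
  shifted$y_nm[second] <- shifted$y_nm[second] - 50
  tr <- estimate_drift_xcorr(shifted, block_frames = 100, bin_nm = 40)
  expect_equal(nrow(tr$trace), 2)
  expect_equal(tr$trace$shift_x_nm[1], 0)
  expect_lt(abs(tr$trace$shift_x_nm[2] - 100), 0.25 * 40)
  expect_lt(abs(tr$trace$shift_y_nm[2] + 50), 0.25 * 40)
})

test_that("a single block gives the identity trace; correct/restore invert exactly", {
  base <- drift_cloud()
  tr1 <- estimate_drift_xcorr(base, block_frames = 500)
  expect_equal(nrow(tr1$trace), 1)
  expect_equal(apply_drift(base, tr1), base)
  tr2 <- estimate_drift_xcorr(base, block_frames = 50, bin_nm = 50)
  corrected <- apply_drift(base, tr2)
  restored <- apply_drift(corrected, tr2, direction = "restore")
  expect_equal(restored$x_nm, base$x_nm, tolerance = 1e-12)
  expect_equal(restored$y_nm, base$y_nm, tolerance = 1e-12)
})

test_that("piecewise-constant drift is inverted up to histogram quantisation", {
  base <- drift_cloud(n = 600, seed = 8)
  drifted <- base
  for (b in 1:3) {
    rows <- drifted$frame >= (b - 1) * 67 & drifted$frame < b * 67
    drifted$x_nm[rows] <- drifted$x_nm[rows] + (b - 1) * 80
    drifted$y_nm[rows] <- drifted$y_nm[rows] + (b - 1) * -60
  }
  tr <- estimate_drift_xcorr(drifted, block_frames = 67, bin_nm = 30)
  mid <- drifted$frame %% 67 > 15 & drifted$frame %% 67 < 50  # block cores
  corr <- apply_drift(drifted, tr)
  err <- sqrt((corr$x_nm - base$x_nm)^2 + (corr$y_nm - base$y_nm)^2)
  expect_lt(median(err[mid]), 30)
})

test_that("fiducial correction handles constant tracks, ramps and gaps", {
  locs <- drift_cloud(n = 100, seed = 3)
  const <- tibble::tibble(frame = 0:199, x_nm = 500, y_nm = 700)
  expect_equal(fiducial_drift(locs, const), locs)
  ramp <- tibble::tibble(frame = 0:199, x_nm = 0 + (0:199) * 1, y_nm = 0)
  out <- fiducial_drift(locs, ramp)
  expect_equal(out$x_nm, locs$x_nm - (locs$frame - mean(0:199)), tolerance = 1e-9)
  # a gap in the middle is interpolated (and reported)
  gappy <- ramp[-(96:105), ]  # frames 95..104, symmetric about the mean
  expect_message(out2 <- fiducial_drift(locs, gappy), "interpolating")
  expect_equal(out2$x_nm, out$x_nm, tolerance = 1e-6)
  expect_error(fiducial_drift(locs, tibble::tibble(frame = 900:950, x_nm = 0, y_nm = 0)),
               "overlap")
})

test_that("blinking grouping merges consecutive appearances and respects gaps", {
  two <- tibble::tibble(frame = c(3L, 4L), x_nm = 1000, y_nm = 1000,
                        z_nm = 50, intensity = c(200, 300))
  g <- group_blinking(two, dxy_max_nm = 150, max_gap_frames = 50)
  expect_equal(nrow(g), 1)
  expect_equal(g$multiplicity, 2L)
  expect_equal(g$x_nm, 1000)
  expect_equal(g$intensity, 500)
  expect_equal(g$frame, 3L)
  far <- two
  far$frame <- c(3L, 63L)
  g2 <- group_blinking(far, dxy_max_nm = 150, max_gap_frames = 50)
  expect_equal(nrow(g2), 2)
})

test_that("grouping is transitive and matches brute-force connected components", {
  # chain: A-B and B-C within range, A-C beyond
  chain <- tibble::tibble(frame = c(1L, 2L, 3L),
                          x_nm = c(0, 120, 240), y_nm = 0, z_nm = 0,
                          intensity = 100)
  g <- group_blinking(chain, dxy_max_nm = 150, max_gap_frames = 50)
  expect_equal(nrow(g), 1)
  expect_equal(g$multiplicity, 3L)
  expect_equal(g$x_nm, 120)
  # random instances vs oracle
  for (k in 1:10) {
    set.seed(600 + k)
    n <- 40
    locs <- tibble::tibble(frame = sample(0:30, n, replace = TRUE),
                           x_nm = runif(n, 0, 1500), y_nm = runif(n, 0, 1500),
                           z_nm = runif(n, -300, 300), intensity = 1)
    locs <- locs[order(locs$frame), ]
    g <- group_blinking(locs, dxy_max_nm = 200, max_gap_frames = 10)
    linked <- function(i, j) {
      sqrt((locs$x_nm[i] - locs$x_nm[j])^2 + (locs$y_nm[i] - locs$y_nm[j])^2) < 200 &&
        abs(locs$frame[i] - locs$frame[j]) <= 10
    }
    comp <- oracle_components(n, linked)
    expect_equal(nrow(g), length(unique(comp)))
    expect_equal(sum(g$intensity), sum(locs$intensity))
    expect_equal(sum(g$multiplicity), n)
  }
})

# a hollow sphere with Gaussian localisation jitter: a structured set whose
# resolution is set by the 30 nm jitter
sphere_locs <- function(n, radius = 300, jitter = 30, seed = 1) {
  set.seed(seed)
  u <- matrix(rnorm(3 * n), ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  xyz <- u * radius + matrix(rnorm(3 * n, 0, jitter), ncol = 3)
  tibble::tibble(frame = seq_len(n), x_nm = xyz[, 1] + 500,
                 y_nm = xyz[, 2] + 500, z_nm = xyz[, 3] + 500, intensity = 1)
}

test_that("self-correlation is unity at every shell", {
  locs <- sphere_locs(2000, seed = 2)
  fsc <- fsc_resolution(locs, voxel_nm = 10, split = "none")
  expect_true(all(abs(fsc$curve$correlation - 1) < 1e-9))
  expect_equal(fsc$resolution_nm, 20)  # Nyquist-limited: 2 voxels
  expect_equal(fsc$curve$correlation[fsc$curve$shell == 0], 1)
})

test_that("structured data resolves better than uniform random points", {
  structured <- sphere_locs(8000, seed = 3)
  set.seed(4)
  uniform <- tibble::tibble(frame = 1:8000,
                            x_nm = runif(8000, -300, 1300),
                            y_nm = runif(8000, -300, 1300),
                            z_nm = runif(8000, -300, 1300), intensity = 1)
  f_s <- fsc_resolution(structured, voxel_nm = 10, seed = 11)
  f_u <- fsc_resolution(uniform, voxel_nm = 10, seed = 11)
  expect_lt(f_s$resolution_nm, f_u$resolution_nm)
  # beyond low frequencies the uniform set decorrelates
  hi <- f_u$curve[f_u$curve$frequency_nm > 0.005, ]
  expect_lt(mean(abs(hi$correlation)), 0.2)
})

test_that("sphere resolution lands in the expected band, stably across seeds", {
  locs <- sphere_locs(8000, seed = 6)
  res <- vapply(c(21, 22, 23), function(s) {
    fsc_resolution(locs, voxel_nm = 10, seed = s)$resolution_nm
  }, numeric(1))
  expect_true(all(res >= 50 & res <= 200))
  expect_lt((max(res) - min(res)) / mean(res), 0.3)  # within +/- 15 %
})

test_that("block-wise FSC analyses only sufficiently occupied blocks", {
  dense <- sphere_locs(4000, radius = 250, seed = 7)
  b <- blockwise_fsc(dense, block_nm = 5000, min_locs = 1000, voxel_nm = 10, seed = 1)
  expect_equal(nrow(b$blocks), 1)
  expect_equal(b$mean_resolution_nm, b$blocks$resolution_nm[1])
  empty <- blockwise_fsc(dense, block_nm = 5000, min_locs = 1e6, voxel_nm = 10)
  expect_equal(nrow(empty$blocks), 0)
  expect_true(is.na(empty$mean_resolution_nm))
  # two identical structures in neighbouring blocks resolve equally
  shifted <- dense
  shifted$x_nm <- shifted$x_nm + 5000
  both <- dplyr::bind_rows(dense, shifted)
  b2 <- blockwise_fsc(both, block_nm = 5000, min_locs = 1000, voxel_nm = 10, seed = 9)
  expect_equal(nrow(b2$blocks), 2)
  expect_lt(abs(diff(b2$blocks$resolution_nm)) / mean(b2$blocks$resolution_nm), 0.2)
})
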