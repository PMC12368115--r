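# Pair features, polynomial calibration and diagnostics.

peak_row <- function(x, y, i) tibble::tibble(x_px = x, y_px = y, intensity = i)

test_that("pair features follow the stated geometry and ordering rules", {
  f <- pair_features(peak_row(0, 0, 200), peak_row(3, 3, 100), 100)
  expect_equal(f$theta_deg, 45)
  expect_equal(f$d_nm, sqrt(18) * 100, tolerance = 1e-9)  # 424.26 nm
  expect_equal(c(f$mid_x_nm, f$mid_y_nm), c(150, 150))
  expect_equal(f$ratio, 2)  # smaller-x lobe over the other
  # swapping the inputs changes nothing
  g <- pair_features(peak_row(3, 3, 100), peak_row(0, 0, 200), 100)
  expect_equal(f, g)
  h <- pair_features(peak_row(0, 0, 200), peak_row(4, 0, 100), 100)
  expect_equal(h$ratio, 2)
  expect_equal(h$theta_deg, 0)
  expect_error(pair_features(peak_row(1, 1, 5), peak_row(1, 1, 5), 100),
               "coincident")
})

# synthetic bead series with exactly linear feature laws, fed in as peaks;
# keeps theta below 90 degrees so the smaller-x lobe never switches side
linear_law_peaks <- function(n = 25, theta0 = 20, dtheta = 2.5) {
  th <- theta0 + dtheta * (0:(n - 1))
  d_px <- 4 + 0.01 * th
  mid <- 20
  r <- 1 + 0.002 * th
  a <- tibble::tibble(
    frame = 0:(n - 1),
    x_px = mid - d_px / 2 * cospi(th / 180),
    y_px = mid - d_px / 2 * sinpi(th / 180),
    intensity = 1000 * r / (1 + r)
  )
  b <- tibble::tibble(
    frame = 0:(n - 1),
    x_px = mid + d_px / 2 * cospi(th / 180),
    y_px = mid + d_px / 2 * sinpi(th / 180),
    intensity = 1000 / (1 + r)
  )
  dplyr::arrange(dplyr::bind_rows(a, b), frame)
}

test_that("a degree-1 fit recovers exactly linear laws to numerical precision", {
  peaks <- linear_law_peaks()  # theta 20..80 deg
  m <- build_calibration(peaks, z_step_nm = 50, degree = 1, pixel_size_nm = 100)
  th <- seq(22, 78, length.out = 11)
  ev <- evaluate_model(m, th)
  z_true <- (th - 20) / 2.5 * 50
  d_true <- (4 + 0.01 * th) * 100
  r_true <- 1 + 0.002 * th
  expect_equal(ev$z_nm, z_true, tolerance = 1e-8)
  expect_equal(ev$d_nm, d_true, tolerance = 1e-8)
  expect_equal(ev$ratio, r_true, tolerance = 1e-8)
  expect_equal(m$residual_rms[["r"]], 0, tolerance = 1e-10)
})

test_that("calibration closes on the generator: z recovered within 1 nm", {
  model <- fix_model()
  feats <- model$features
  ev <- evaluate_model(model, feats$theta_deg)
  expect_lte(max(abs(ev$z_nm - feats$z_nm)), 1)
  expect_lt(model$residual_rms[["z"]], 1)
  expect_lt(model$residual_rms[["r"]], 0.01)
})

test_that("frame_range trims the usable angle range", {
  cp <- fix_calibration_peaks()
  full <- fix_model()
  trimmed <- build_calibration(cp$peaks, 33.3, frame_range = c(0, 108),
                               pixel_size_nm = 210, z_offset_nm = -2000)
  expect_lt(diff(trimmed$theta_range), diff(full$theta_range))
  excluded <- full$features$theta_deg[full$features$frame > 108]
  ev <- evaluate_model(trimmed, excluded)
  expect_true(all(!ev$in_range))
})

test_that("an angle sequence folding past 180 degrees is rejected", {
  peaks <- linear_law_peaks(n = 25, theta0 = 100, dtheta = 4)  # 100..196 folds
  expect_error(build_calibration(peaks, 50, degree = 1, pixel_size_nm = 100),
               "monotonic")
})

test_that("fitted z(theta) is strictly monotonic over the angle range", {
  model <- fix_model()
  th <- seq(model$theta_range[1], model$theta_range[2], length.out = 1000)
  z <- evaluate_model(model, th)$z_nm
  expect_true(all(diff(z) > 0) || all(diff(z) < 0))
})

test_that("angles outside the usable range are flagged, not extrapolated", {
  model <- fix_model()
  ev <- evaluate_model(model, model$theta_range[2] + 0.5)
  expect_false(ev$in_range)
  expect_true(is.na(ev$z_nm))
})

test_that("diagnostics report clean fits and serialise to text and PNG", {
  model <- fix_model()
  rep <- calibration_diagnostics(model)
  expect_true(rep$theta_monotonic)
  expect_true(rep$z_monotonic)
  expect_lt(rep$curve_rms[["z"]], 1)
  dir <- withr::local_tempdir()
  files <- save_calibration_diagnostics(model, dir)
  expect_true(all(file.exists(files)))
  expect_gt(file.size(files[2]), 0)
})

test_that("refitting the model on its own predictions reproduces it", {
  model <- fix_model()
  th <- model$features$theta_deg
  ev <- evaluate_model(model, th)
  # reconstruct a peak table from the predicted curves
  mid_x <- (ev$dx_nm + model$features$mid_x_nm[1]) / 210
  mid_y <- (ev$dy_nm + model$features$mid_y_nm[1]) / 210
  hx <- ev$d_nm / 2 / 210 * cospi(th / 180)
  hy <- ev$d_nm / 2 / 210 * sinpi(th / 180)
  # give the smaller-x lobe the ratio-weighted flux, as pair_features measures
  a_small <- (-hx < hx) | (hx == 0 & -hy <= hy)
  ia <- ifelse(a_small, 1000 * ev$ratio / (1 + ev$ratio), 1000 / (1 + ev$ratio))
  ib <- 1000 - ia
  a <- tibble::tibble(frame = model$features$frame, x_px = mid_x - hx,
                      y_px = mid_y - hy, intensity = ia)
  b <- tibble::tibble(frame = model$features$frame, x_px = mid_x + hx,
                      y_px = mid_y + hy, intensity = ib)
  peaks <- dplyr::arrange(dplyr::bind_rows(a, b), frame)
  m2 <- build_calibration(peaks, 33.3, pixel_size_nm = 210, z_offset_nm = -2000)
  th_grid <- seq(model$theta_range[1] + 1, model$theta_range[2] - 1, length.out = 200)
  expect_equal(evaluate_model(m2, th_grid)$z_nm,
               evaluate_model(model, th_grid)$z_nm, tolerance = 1e-3)
  expect_equal(evaluate_model(m2, th_grid)$d_nm,
               evaluate_model(model, th_grid)$d_nm, tolerance = 1e-3)
})

test_that("noisy calibrations still recover the generator laws", {
  gen <- fix_generator()
  # noise chosen so single-lobe centre errors are ~0.02 px; stringent
  # detection threshold, as appropriate for calibration data
  cal <- simulate_calibration(gen, noise_sd = 8, background = 50, seed = 5)
  peaks <- detect_stack(cal$stack, detection_params(threshold = 6))
  model <- suppressWarnings(
    build_calibration(peaks, 33.3, pixel_size_nm = 210, z_offset_nm = -2000)
  )
  feats <- model$features
  ev <- evaluate_model(model, feats$theta_deg)
  expect_lte(sqrt(mean((ev$z_nm - feats$z_nm)^2)), 10)
  # distance and ratio curves within 5 % of the generator over the
  # central 90 % of the angle range
  qr <- quantile(feats$theta_deg, c(0.05, 0.95))
  th <- seq(qr[1], qr[2], length.out = 100)
  evc <- evaluate_model(model, th)
  z_of_th <- gen$z_range_nm[1] +
    (th - gen$theta0_deg) / gen$theta_span_deg * diff(gen$z_range_nm)
  truth <- psf_truth(z_of_th, gen)
  expect_lt(max(abs(evc$d_nm / truth$d_nm - 1)), 0.05)
  expect_lt(max(abs(evc$ratio / truth$ratio - 1)), 0.05)
})

test_that("tidy and glance expose coefficients and fit summaries", {
  model <- fix_model()
  td <- tidy(model)
  expect_equal(nrow(td), 5 * (model$degree + 1))
  expect_setequal(unique(td$curve), c("z", "dx", "dy", "d", "r"))
  gl <- glance(model)
  expect_equal(gl$degree, 15)
  expect_equal(gl$n_frames, 119)
})
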