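# Ground-truth matching and benchmark metrics.

loc_tab <- function(x, y, z, frame = 0L, intensity = 100) {
  tibble::tibble(frame = frame, x_nm = x, y_nm = y, z_nm = z,
                 intensity = intensity)
}

random_tables <- function(n_det, n_tru, seed, spread = 2000) {
  set.seed(seed)
  list(
    detected = loc_tab(runif(n_det, 0, spread), runif(n_det, 0, spread),
                       runif(n_det, -500, 500)),
    truth = loc_tab(runif(n_tru, 0, spread), runif(n_tru, 0, spread),
                    runif(n_tru, -500, 500))
  )
}

test_that("perfect detections match one-to-one with zero distances", {
  t <- random_tables(8, 8, 1)
  m <- match_localisations(t$truth, t$truth)
  expect_equal(c(m$n_tp, m$n_fp, m$n_fn), c(8, 0, 0))
  expect_true(all(m$pairs$d_3d_nm == 0))
  expect_equal(unlist(loc_metrics(m)[1, 1:3]), c(precision = 1, sensitivity = 1, jaccard = 1))
})

test_that("one truth with two nearby detections gives one TP and one FP", {
  truth <- loc_tab(1000, 1000, 0)
  det <- loc_tab(c(1010, 1040), c(1000, 1000), c(0, 0))
  m <- match_localisations(det, truth)
  expect_equal(c(m$n_tp, m$n_fp, m$n_fn), c(1, 1, 0))
  expect_equal(m$pairs$detected_id, 1L)  # the nearer one wins
})

test_that("greedy matching agrees with the maximum-matching optimum almost always", {
  agree <- 0L
  trials <- 300L
  for (k in seq_len(trials)) {
    t <- random_tables(10, 10, 1000 + k, spread = 2500)
    m <- match_localisations(t$detected, t$truth, tol_xy_nm = 250, tol_z_nm = 500,
                             same_frame = FALSE)
    opt <- oracle_optimal_tp(t$detected, t$truth, 250, 500)
    if (m$n_tp == opt) agree <- agree + 1L
    expect_lte(m$n_tp, opt)
  }
  expect_gte(agree / trials, 0.95)
})

test_that("metric arithmetic and undefined flags are exact", {
  fake <- structure(list(n_tp = 9, n_fp = 1, n_fn = 1,
                         pairs = tibble::tibble(detected_id = integer())),
                    class = "dh_match")
  m <- loc_metrics(fake)
  expect_equal(m$precision, 0.9)
  expect_equal(m$sensitivity, 0.9)
  expect_equal(m$jaccard, 9 / 11)
  full <- loc_metrics(structure(list(n_tp = 5, n_fp = 0, n_fn = 0), class = "dh_match"))
  expect_equal(unlist(full[1, 1:3]), c(precision = 1, sensitivity = 1, jaccard = 1))
  none <- loc_metrics(structure(list(n_tp = 0, n_fp = 0, n_fn = 0), class = "dh_match"))
  expect_true(all(is.na(unlist(none[1, 1:3]))))
  expect_setequal(attr(none, "undefined"), c("precision", "sensitivity", "jaccard"))
})

test_that("metrics stay in [0,1] with jaccard below both, under row permutations", {
  for (k in 1:20) {
    t <- random_tables(sample(3:12, 1), sample(3:12, 1), 3000 + k)
    m <- loc_metrics(match_localisations(t$detected, t$truth))
    vals <- unlist(m[1, 1:3])
    vals <- vals[!is.na(vals)]
    expect_true(all(vals >= 0 & vals <= 1))
    if (!anyNA(unlist(m[1, 1:3]))) {
      expect_lte(m$jaccard, min(m$precision, m$sensitivity) + 1e-12)
    }
    perm_d <- t$detected[sample(nrow(t$detected)), ]
    perm_t <- t$truth[sample(nrow(t$truth)), ]
    m2 <- loc_metrics(match_localisations(perm_d, perm_t))
    expect_equal(unlist(m[1, 1:6]), unlist(m2[1, 1:6]))
  }
})

test_that("accuracy medians summarise the matched distances", {
  truth <- loc_tab(c(0, 1000, 2000), c(0, 0, 0), c(0, 0, 0))
  det <- loc_tab(c(0, 1000, 2000), c(0, 0, 0), c(1, 2, 3))
  m <- match_localisations(det, truth)
  s <- accuracy_stats(m)$summary
  expect_equal(s$median_abs_d_z_nm, 2)
  expect_equal(s$median_d_xy_nm, 0)
  # all distances equal -> medians equal that distance
  det2 <- loc_tab(c(10, 1010, 2010), c(0, 0, 0), c(0, 0, 0))
  s2 <- accuracy_stats(match_localisations(det2, truth))$summary
  expect_equal(s2$median_d_xy_nm, 10)
  expect_equal(s2$median_d_3d_nm, 10)
  expect_error(accuracy_stats(match_localisations(loc_tab(9e6, 9e6, 0), truth)),
               "undefined")
})

test_that("median 3D accuracy improves monotonically with S/N", {
  gen <- fix_generator_small()
  model <- fix_model()
  med <- vapply(c(5.8, 6.6, 23), function(snr) {
    sim <- simulate_dataset(gen, 12, 5, snr, seed = 808)
    locs <- unmix_stack(detect_stack(sim$stack), model, benchmark_params(model))
    m <- match_localisations(locs, sim$scene$truth)
    accuracy_stats(m)$summary$median_d_3d_nm
  }, numeric(1))
  expect_true(all(diff(med) < 0))
})

test_that("sensitivity-vs-z profiles reflect axial detector behaviour", {
  set.seed(9)
  truth <- loc_tab(runif(400, 0, 5000), runif(400, 0, 5000),
                   runif(400, -2000, 2000))
  m_all <- match_localisations(truth, truth)
  prof <- sensitivity_vs_z(m_all, bin_nm = 500)
  expect_true(all(prof$sensitivity == 1))
  expect_equal(sum(prof$n_truth), 400)
  # a detector blind beyond |z| > 1500
  det <- truth[abs(truth$z_nm) <= 1500, ]
  prof2 <- sensitivity_vs_z(match_localisations(det, truth), bin_nm = 500)
  outer <- prof2[prof2$z_lo_nm >= 1500 | prof2$z_hi_nm <= -1500, ]
  inner <- prof2[prof2$z_lo_nm >= -1000 & prof2$z_hi_nm <= 1000, ]
  expect_true(all(outer$sensitivity == 0))
  expect_true(all(inner$sensitivity == 1))
})

test_that("windowed evaluation equals manual post-hoc restriction of a full match", {
  t <- random_tables(60, 60, 17)
  win <- c(-250, 250)
  m_win <- match_localisations(t$detected, t$truth, z_window_nm = win)
  m_full <- match_localisations(t$detected, t$truth)
  truth_in <- t$truth$z_nm >= win[1] & t$truth$z_nm <= win[2]
  det_in <- t$detected$z_nm >= win[1] & t$detected$z_nm <= win[2]
  tp_manual <- sum(truth_in[m_full$pairs$truth_id])
  matched <- seq_len(nrow(t$detected)) %in% m_full$pairs$detected_id
  expect_equal(m_win$n_tp, tp_manual)
  expect_equal(m_win$n_fn, sum(truth_in) - tp_manual)
  expect_equal(m_win$n_fp, sum(det_in & !matched))
})

test_that("translation correction inverts constant offsets exactly", {
  t <- random_tables(30, 30, 23)
  shifted <- t$truth
  shifted$x_nm <- shifted$x_nm + 10
  shifted$y_nm <- shifted$y_nm - 5
  shifted$z_nm <- shifted$z_nm + 20
  m <- match_localisations(shifted, t$truth)
  corrected <- translation_correct(shifted, m)
  expect_equal(corrected$x_nm, t$truth$x_nm, tolerance = 1e-9)
  expect_equal(attr(corrected, "offset_nm"),
               c(x = 10, y = -5, z = 20), tolerance = 1e-9)
  m2 <- match_localisations(corrected, t$truth)
  expect_lt(accuracy_stats(m2)$summary$median_d_3d_nm, 1e-9)
  # zero offset: table unchanged
  m0 <- match_localisations(t$truth, t$truth)
  c0 <- translation_correct(t$truth, m0)
  expect_equal(c0$x_nm, t$truth$x_nm)
  # offset on half the points: the mean correction is half the offset
  half <- t$truth
  half$x_nm[1:15] <- half$x_nm[1:15] + 40
  mh <- match_localisations(half, t$truth)
  ch <- translation_correct(half, mh)
  expect_equal(unname(attr(ch, "offset_nm")["x"]), 20, tolerance = 1e-9)
})

test_that("eligibility filters drop borders and the dimmest fraction, order-free", {
  set.seed(31)
  truth <- loc_tab(runif(100, 0, 10000), runif(100, 0, 10000),
                   runif(100, -500, 500), intensity = sample(1:100))
  just_dim <- eligibility_filters(truth, dimmest_fraction = 0.25)
  expect_equal(nrow(just_dim), 75)
  expect_true(min(just_dim$intensity) > 25 - 1)
  expect_equal(nrow(eligibility_filters(truth, border_nm = 0)), 100)
  both <- eligibility_filters(truth, border_nm = 1000, dimmest_fraction = 0.25,
                              width_nm = 10000, height_nm = 10000)
  just_border <- eligibility_filters(truth, border_nm = 1000,
                                     width_nm = 10000, height_nm = 10000)
  # joint application = intersection of the single-criterion survivor sets
  manual <- dplyr::intersect(just_border, just_dim)
  expect_setequal(paste(both$x_nm, both$intensity),
                  paste(manual$x_nm, manual$intensity))
  expect_error(eligibility_filters(truth, dimmest_fraction = 1), "0, 1")
})
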