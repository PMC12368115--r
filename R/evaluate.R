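# Benchmarking against ground truth: one-to-one matching, precision /
# sensitivity / Jaccard, localisation-accuracy distributions, sensitivity
# as a function of z, global translation correction, and the eligibility
# conventions (border exclusion, dimmest-fraction exclusion).

#' Match detected localisations to ground truth
#'
#' Greedy one-to-one assignment: within each frame (or globally when
#' `same_frame = FALSE`), all detected-truth pairs with lateral distance
#' `<= tol_xy_nm` and axial distance `<= tol_z_nm` are candidates, processed
#' in ascending order of 3D distance (ties broken by row indices); a pair is
#' accepted only if neither member is already matched. Unmatched detected
#' rows are false positives, unmatched truths false negatives.
#'
#' @param detected Localisation tibble; rows with `kept == FALSE` are
#'   ignored if a `kept` column is present.
#' @param truth Ground-truth tibble with `frame`, `x_nm`, `y_nm`, `z_nm`.
#' @param tol_xy_nm,tol_z_nm Matching tolerances, nm. There is no universal
#'   convention for these radii, so they are explicit parameters and are
#'   recorded in the report.
#' @param same_frame Require matches to share the frame index.
#' @param z_window_nm Optional `c(lo, hi)`: restrict the evaluation to the
#'   axial window (the "restricted z-range" convention). Matching is still
#'   performed on the full tables; the counts are then restricted: TP are
#'   matches whose truth lies in the window, FN are unmatched in-window
#'   truths, FP are unmatched detections inside the window. A detection
#'   matched to an out-of-window truth therefore counts neither way, which
#'   avoids spurious FP/FN flips for molecules localised within their error
#'   of the window boundary.
#' @return An object of class `dh_match`: `pairs` (tibble with row ids into
#'   the stored tables, per-axis signed errors and distances), counts
#'   `n_tp`, `n_fp`, `n_fn`, the tolerances, and the `detected` / `truth`
#'   tables as used (kept rows only).
#' @export
match_localisations <- function(detected, truth, tol_xy_nm = 250, tol_z_nm = 500,
                                same_frame = TRUE, z_window_nm = NULL) {
  if ("kept" %in% names(detected)) detected <- detected[detected$kept, ]
  nd <- nrow(detected); nt <- nrow(truth)
  cand <- NULL
  if (nd > 0 && nt > 0) {
    frames_d <- if (same_frame) detected$frame else rep(0L, nd)
    frames_t <- if (same_frame) truth$frame else rep(0L, nt)
    pieces <- list()
    for (f in intersect(unique(frames_d), unique(frames_t))) {
      di <- which(frames_d == f); ti <- which(frames_t == f)
      dxy <- sqrt(outer(detected$x_nm[di], truth$x_nm[ti], "-")^2 +
                    outer(detected$y_nm[di], truth$y_nm[ti], "-")^2)
      dz <- outer(detected$z_nm[di], truth$z_nm[ti], "-")
      ok <- which(dxy <= tol_xy_nm & abs(dz) <= tol_z_nm, arr.ind = TRUE)
      if (nrow(ok) == 0L) next
      pieces[[length(pieces) + 1L]] <- tibble(
        detected_id = di[ok[, 1]], truth_id = ti[ok[, 2]],
        d_xy_nm = dxy[ok], d_z_nm = dz[ok]
      )
    }
    if (length(pieces) > 0) cand <- bind_rows(pieces)
  }
  if (is.null(cand) || nrow(cand) == 0L) {
    pairs <- tibble(detected_id = integer(), truth_id = integer(),
                    frame = integer(), dx_nm = numeric(), dy_nm = numeric(),
                    dz_nm = numeric(), d_xy_nm = numeric(), d_z_nm = numeric(),
                    d_3d_nm = numeric())
  } else {
    cand$d_3d_nm <- sqrt(cand$d_xy_nm^2 + cand$d_z_nm^2)
    ord <- order(cand$d_3d_nm, cand$detected_id, cand$truth_id)
    acc <- greedy_accept(cand$detected_id, cand$truth_id, ord, nd, nt)
    pairs <- cand[acc, ]
    pairs$frame <- detected$frame[pairs$detected_id]
    pairs$dx_nm <- detected$x_nm[pairs$detected_id] - truth$x_nm[pairs$truth_id]
    pairs$dy_nm <- detected$y_nm[pairs$detected_id] - truth$y_nm[pairs$truth_id]
    pairs$dz_nm <- pairs$d_z_nm
    pairs <- pairs[order(pairs$d_3d_nm),
                   c("detected_id", "truth_id", "frame", "dx_nm", "dy_nm",
                     "dz_nm", "d_xy_nm", "d_z_nm", "d_3d_nm")]
  }
  if (is.null(z_window_nm)) {
    n_tp <- nrow(pairs)
    n_fp <- nd - n_tp
    n_fn <- nt - n_tp
  } else {
    truth_in <- truth$z_nm >= z_window_nm[1] & truth$z_nm <= z_window_nm[2]
    det_in <- !is.na(detected$z_nm) &
      detected$z_nm >= z_window_nm[1] & detected$z_nm <= z_window_nm[2]
    matched_any <- logical(nd)
    matched_any[pairs$detected_id] <- TRUE
    pairs <- pairs[truth_in[pairs$truth_id], ]
    n_tp <- nrow(pairs)
    n_fn <- sum(truth_in) - n_tp
    n_fp <- sum(det_in & !matched_any)
  }
  structure(
    list(pairs = pairs, n_tp = n_tp, n_fp = n_fp,
         n_fn = n_fn, tol_xy_nm = tol_xy_nm, tol_z_nm = tol_z_nm,
         same_frame = same_frame, z_window_nm = z_window_nm,
         detected = detected, truth = truth),
    class = "dh_match"
  )
}

#' @export
print.dh_match <- function(x, ...) {
  cat(sprintf("<dh_match> TP %d, FP %d, FN %d (tol xy %g nm, z %g nm)\n",
              x$n_tp, x$n_fp, x$n_fn, x$tol_xy_nm, x$tol_z_nm))
  m <- loc_metrics(x)
  cat(sprintf("  precision %.3f, sensitivity %.3f, Jaccard %.3f\n",
              m$precision, m$sensitivity, m$jaccard))
  invisible(x)
}

#' Detection-quality metrics of a match report
#'
#' precision = TP / (TP + FP); sensitivity (recall) = TP / (TP + FN);
#' Jaccard index = TP / (TP + FP + FN). A zero denominator yields `NA` and
#' the attribute `"undefined"` lists which metrics were undefined.
#'
#' @param report A `dh_match`.
#' @return A one-row tibble with `precision`, `sensitivity`, `jaccard`,
#'   `n_tp`, `n_fp`, `n_fn`.
#' @export
loc_metrics <- function(report) {
  stopifnot(inherits(report, "dh_match"))
  safe <- function(num, den) if (den == 0) NA_real_ else num / den
  out <- tibble(
    precision = safe(report$n_tp, report$n_tp + report$n_fp),
    sensitivity = safe(report$n_tp, report$n_tp + report$n_fn),
    jaccard = safe(report$n_tp, report$n_tp + report$n_fp + report$n_fn),
    n_tp = report$n_tp, n_fp = report$n_fp, n_fn = report$n_fn
  )
  undef <- c("precision", "sensitivity", "jaccard")[is.na(unlist(out[1, 1:3]))]
  attr(out, "undefined") <- undef
  out
}

#' @method glance dh_match
#' @export
glance.dh_match <- function(x, ...) loc_metrics(x)

#' @method tidy dh_match
#' @export
tidy.dh_match <- function(x, ...) x$pairs

#' Localisation-accuracy summaries of matched pairs
#'
#' @param report A `dh_match` with at least one true positive.
#' @return A list: `summary` (one-row tibble of the median lateral, absolute
#'   axial and 3D distances, nm) and `distances` (the full per-pair
#'   distributions, for plotting).
#' @export
accuracy_stats <- function(report) {
  stopifnot(inherits(report, "dh_match"))
  if (report$n_tp < 1) abort("no matched pairs: accuracy is undefined.")
  p <- report$pairs
  list(
    summary = tibble(
      median_d_xy_nm = median(p$d_xy_nm),
      median_abs_d_z_nm = median(abs(p$d_z_nm)),
      median_d_3d_nm = median(p$d_3d_nm)
    ),
    distances = p[c("d_xy_nm", "d_z_nm", "d_3d_nm")]
  )
}

#' Sensitivity as a function of the axial coordinate
#'
#' Bins the eligible truths by z and reports the fraction matched in each
#' bin; bins containing no truths are omitted.
#'
#' @param report A `dh_match`.
#' @param bin_nm Bin width, nm.
#' @return A tibble with `z_lo_nm`, `z_mid_nm`, `z_hi_nm`, `n_truth`,
#'   `n_matched`, `sensitivity`.
#' @export
sensitivity_vs_z <- function(report, bin_nm = 250) {
  stopifnot(inherits(report, "dh_match"))
  truth <- report$truth
  if (nrow(truth) == 0L) return(tibble(z_lo_nm = numeric(), z_mid_nm = numeric(),
                                       z_hi_nm = numeric(), n_truth = integer(),
                                       n_matched = integer(), sensitivity = numeric()))
  matched <- seq_len(nrow(truth)) %in% report$pairs$truth_id
  bin <- floor(truth$z_nm / bin_nm)
  agg <- tibble(bin = bin, matched = matched) |>
    group_by(.data$bin) |>
    summarise(n_truth = n(), n_matched = sum(.data$matched), .groups = "drop")
  tibble(
    z_lo_nm = agg$bin * bin_nm,
    z_mid_nm = (agg$bin + 0.5) * bin_nm,
    z_hi_nm = (agg$bin + 1) * bin_nm,
    n_truth = agg$n_truth,
    n_matched = agg$n_matched,
    sensitivity = agg$n_matched / agg$n_truth
  )
}

#' Correct a global translation between detections and truth
#'
#' Subtracts the mean (detected - truth) offset vector over the true
#' positives from all detected coordinates. This compensates a uniform
#' translation of the whole localisation list, e.g. from a calibration
#' acquired with a laterally offset bead.
#'
#' @param detected The localisation tibble that was matched.
#' @param report The `dh_match` for `detected`.
#' @return `detected` with `x_nm`, `y_nm`, `z_nm` shifted; the applied
#'   offset is attached as attribute `"offset_nm"`.
#' @export
translation_correct <- function(detected, report) {
  stopifnot(inherits(report, "dh_match"))
  if (report$n_tp < 1) abort("no true positives: translation is undefined.")
  off <- c(x = mean(report$pairs$dx_nm), y = mean(report$pairs$dy_nm),
           z = mean(report$pairs$dz_nm))
  detected$x_nm <- detected$x_nm - off["x"]
  detected$y_nm <- detected$y_nm - off["y"]
  detected$z_nm <- detected$z_nm - off["z"]
  attr(detected, "offset_nm") <- off
  detected
}

#' Eligibility filters for ground-truth tables
#'
#' The established benchmarking conventions: truths within `border_nm` of
#' the canvas edge are excluded, and the dimmest fraction of truths (by
#' intensity) is excluded since those are not expected to be detectable.
#' Both criteria are evaluated on the supplied table and intersected, so the
#' survivor set does not depend on the order the criteria are written in.
#'
#' @param truth Ground-truth tibble with `x_nm`, `y_nm` and an intensity
#'   column (`intensity` or `flux`).
#' @param border_nm Border exclusion width, nm (0 disables).
#' @param dimmest_fraction Fraction in \[0, 1) of the dimmest truths to drop
#'   (`floor(n * fraction)` rows, ranked on the supplied table).
#' @param width_nm,height_nm Canvas extent, nm; required when
#'   `border_nm > 0`.
#' @return The filtered truth tibble (row order preserved).
#' @export
eligibility_filters <- function(truth, border_nm = 0, dimmest_fraction = 0,
                                width_nm = NULL, height_nm = NULL) {
  if (dimmest_fraction < 0 || dimmest_fraction >= 1) {
    abort("`dimmest_fraction` must lie in [0, 1).")
  }
  keep <- rep(TRUE, nrow(truth))
  if (border_nm > 0) {
    if (is.null(width_nm) || is.null(height_nm)) {
      abort("`width_nm` and `height_nm` are required when `border_nm` > 0.")
    }
    keep <- keep &
      truth$x_nm >= border_nm & truth$x_nm <= width_nm - border_nm &
      truth$y_nm >= border_nm & truth$y_nm <= height_nm - border_nm
  }
  if (dimmest_fraction > 0 && nrow(truth) > 0) {
    ival <- truth[["intensity"]] %||% truth[["flux"]]
    if (is.null(ival)) abort("truth table has no `intensity` or `flux` column.")
    k <- floor(nrow(truth) * dimmest_fraction)
    if (k > 0) keep[order(ival)[seq_len(k)]] <- FALSE
  }
  truth[keep, ]
}

#' Plot the localisation-error distributions of a match report
#'
#' @param object A `dh_match` with matched pairs.
#' @param ... Unused.
#' @return A ggplot object (lateral / axial / 3D error histograms).
#' @method autoplot dh_match
#' @export
autoplot.dh_match <- function(object, ...) {
  if (object$n_tp < 1) abort("no matched pairs to plot.")
  long <- tidyr::pivot_longer(
    tibble(lateral = object$pairs$d_xy_nm,
           axial = abs(object$pairs$d_z_nm),
           `3D` = object$pairs$d_3d_nm),
    dplyr::everything(), names_to = "component", values_to = "error_nm"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$error_nm)) +
    ggplot2::geom_histogram(bins = 50) +
    ggplot2::facet_wrap(~component, scales = "free") +
    ggplot2::labs(x = "localisation error (nm)", y = "count")
}
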