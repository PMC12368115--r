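# Calibration: turn the per-frame lobe pairs of a bead z-stack into
# polynomial curves of z, midpoint wobble, interlobe distance and intensity
# ratio as functions of the rotation angle.

#' Geometric and photometric features of a lobe pair
#'
#' The rotation angle is `atan2(dy, dx)` folded into \[0, 180) (a lobe pair
#' is a line, not a vector), the interlobe distance and midpoint are
#' converted to nm with the pixel size, and the intensity ratio follows a
#' fixed ordering convention: intensity of the lobe with smaller x (ties
#' broken by smaller y) divided by the other. The result is therefore
#' invariant under swapping the two input peaks.
#'
#' @param peak_a,peak_b Data frames (or one-row tibbles) of equal height with
#'   columns `x_px`, `y_px`, `intensity`; row i of `peak_a` is paired with
#'   row i of `peak_b`.
#' @param pixel_size_nm Lateral pixel size, nm.
#' @return A tibble with columns `theta_deg`, `mid_x_nm`, `mid_y_nm`,
#'   `d_nm`, `ratio`, `total_intensity`.
#' @export
pair_features <- function(peak_a, peak_b, pixel_size_nm) {
  assert_number(pixel_size_nm, "pixel_size_nm", positive = TRUE)
  dx <- peak_b$x_px - peak_a$x_px
  dy <- peak_b$y_px - peak_a$y_px
  d_px <- sqrt(dx^2 + dy^2)
  if (any(d_px == 0)) abort("coincident peaks: interlobe distance is zero.")
  swap <- (peak_b$x_px < peak_a$x_px) |
    (peak_b$x_px == peak_a$x_px & peak_b$y_px < peak_a$y_px)
  int_small_x <- ifelse(swap, peak_b$intensity, peak_a$intensity)
  int_other <- ifelse(swap, peak_a$intensity, peak_b$intensity)
  tibble(
    theta_deg = fold_angle_deg(atan2(dy, dx) * 180 / pi),
    mid_x_nm = (peak_a$x_px + peak_b$x_px) / 2 * pixel_size_nm,
    mid_y_nm = (peak_a$y_px + peak_b$y_px) / 2 * pixel_size_nm,
    d_nm = d_px * pixel_size_nm,
    ratio = int_small_x / int_other,
    total_intensity = peak_a$intensity + peak_b$intensity
  )
}

#' Build a calibration model from a bead z-stack's peak table
#'
#' Each usable frame must contain exactly two peaks (the two lobes of a
#' single bead); frames with any other count are skipped with a warning.
#' The frame's axial position is `z_offset_nm + frame * z_step_nm`. Degree-
#' `degree` polynomials (Chebyshev basis on the angle rescaled to \[-1, 1\])
#' are fitted by least squares for z, midpoint shift dx and dy (relative to
#' the first retained frame), interlobe distance and intensity ratio, all as
#' functions of the rotation angle. The usable angle range of the model is
#' the span of retained angles.
#'
#' A calibration series covering more than 180 degrees of rotation shows up
#' as a wrap of the folded angle sequence (a jump of nearly 180 degrees
#' between consecutive frames) and is rejected with a pointer to
#' `frame_range`. Small frame-to-frame angle jitter from measurement noise
#' is tolerated; [calibration_diagnostics()] reports strict monotonicity.
#'
#' @param peaks Peak tibble (see [read_peak_table()]).
#' @param z_step_nm Axial step between consecutive frames, nm.
#' @param degree Polynomial degree; the default 15 suits clean bead stacks,
#'   lower degrees (3-10) are more robust for noisy ones.
#' @param frame_range Optional `c(first, last)` (0-based, inclusive) to trim
#'   the usable frames, e.g. after inspecting [calibration_diagnostics()].
#' @param pixel_size_nm Lateral pixel size, nm.
#' @param z_offset_nm Axial position of frame 0; defaults to 0 so z is
#'   relative to the start of the stack.
#' @return An object of class `dh_calibration`.
#' @export
build_calibration <- function(peaks, z_step_nm, degree = 15, frame_range = NULL,
                              pixel_size_nm = 210, z_offset_nm = 0) {
  assert_number(z_step_nm, "z_step_nm", positive = TRUE)
  if (!is.null(frame_range)) {
    peaks <- peaks[peaks$frame >= frame_range[1] & peaks$frame <= frame_range[2], ]
  }
  counts <- table(peaks$frame)
  usable <- as.integer(names(counts)[counts == 2L])
  skipped <- sum(counts != 2L)
  if (skipped > 0) {
    warn(sprintf("%d frame(s) without exactly 2 peaks skipped.", skipped))
  }
  usable <- sort(usable)
  if (length(usable) < degree + 2L) {
    abort(sprintf("only %d usable frame(s); need at least degree + 2 = %d.",
                  length(usable), degree + 2L))
  }
  peaks <- peaks[peaks$frame %in% usable, ]
  peaks <- peaks[order(peaks$frame), ]
  a <- peaks[seq(1, nrow(peaks), by = 2), ]
  b <- peaks[seq(2, nrow(peaks), by = 2), ]
  feats <- pair_features(a, b, pixel_size_nm)
  feats$frame <- usable
  feats$z_nm <- z_offset_nm + usable * z_step_nm

  dtheta <- diff(feats$theta_deg)
  # a fold of the [0, 180) angle past the boundary appears as a near-180
  # jump between consecutive frames
  if (any(abs(dtheta) > 90)) {
    abort(paste(
      "rotation angle is not monotonic with frame number: the calibration",
      "series appears to cover more than 180 degrees of rotation, which",
      "makes the angle-to-z mapping ambiguous; restrict `frame_range` to a",
      "monotonic segment (see calibration_diagnostics())."
    ))
  }

  feats$dx_nm <- feats$mid_x_nm - feats$mid_x_nm[1]
  feats$dy_nm <- feats$mid_y_nm - feats$mid_y_nm[1]

  theta_range <- range(feats$theta_deg)
  fit1 <- function(y) cheb_fit(feats$theta_deg, y, degree, xlim = theta_range)
  curves <- list(
    z = fit1(feats$z_nm),
    dx = fit1(feats$dx_nm),
    dy = fit1(feats$dy_nm),
    d = fit1(feats$d_nm),
    r = fit1(feats$ratio)
  )
  rms <- vapply(names(curves), function(nm) {
    y <- switch(nm, z = feats$z_nm, dx = feats$dx_nm, dy = feats$dy_nm,
                d = feats$d_nm, r = feats$ratio)
    sqrt(mean((y - cheb_eval(curves[[nm]], feats$theta_deg))^2))
  }, numeric(1))

  model <- structure(
    list(degree = as.integer(degree), theta_range = theta_range,
         pixel_size_nm = pixel_size_nm, z_step_nm = z_step_nm,
         z_offset_nm = z_offset_nm, curves = curves, residual_rms = rms,
         n_frames_used = length(usable), features = feats),
    class = "dh_calibration"
  )

  zg <- cheb_eval(curves$z, seq(theta_range[1], theta_range[2], length.out = 1000))
  dz <- diff(zg)
  if (!(all(dz > 0) || all(dz < 0))) {
    warn("fitted z(theta) is not strictly monotonic over the angle range; consider a lower degree or trimming frame_range.")
  }
  model
}

#' @export
print.dh_calibration <- function(x, ...) {
  cat("<dh_calibration>\n")
  cat(sprintf("  degree %d, %s frames, angle range [%.2f, %.2f] deg\n",
              x$degree, x$n_frames_used %||% "?", x$theta_range[1], x$theta_range[2]))
  cat(sprintf("  pixel %g nm, z step %g nm, z offset %g nm\n",
              x$pixel_size_nm, x$z_step_nm, x$z_offset_nm))
  if (!is.null(x$residual_rms)) {
    cat(sprintf("  residual RMS: z %.3g nm, d %.3g nm, ratio %.3g, dx %.3g nm, dy %.3g nm\n",
                x$residual_rms[["z"]], x$residual_rms[["d"]], x$residual_rms[["r"]],
                x$residual_rms[["dx"]], x$residual_rms[["dy"]]))
  }
  invisible(x)
}

#' Evaluate the five calibration curves at given rotation angles
#'
#' @param model A `dh_calibration`.
#' @param theta_deg Numeric vector of angles, degrees.
#' @return A tibble with `theta_deg`, `in_range` and the curve values
#'   `z_nm`, `dx_nm`, `dy_nm`, `d_nm`, `ratio`; angles outside the model's
#'   usable range get `in_range = FALSE` and `NA` values (the caller is
#'   expected to filter these out).
#' @export
evaluate_model <- function(model, theta_deg) {
  stopifnot(inherits(model, "dh_calibration"))
  eps <- 1e-9
  inr <- theta_deg >= model$theta_range[1] - eps & theta_deg <= model$theta_range[2] + eps
  out <- tibble(
    theta_deg = theta_deg,
    in_range = inr,
    z_nm = cheb_eval(model$curves$z, theta_deg),
    dx_nm = cheb_eval(model$curves$dx, theta_deg),
    dy_nm = cheb_eval(model$curves$dy, theta_deg),
    d_nm = cheb_eval(model$curves$d, theta_deg),
    ratio = cheb_eval(model$curves$r, theta_deg)
  )
  out[!inr, c("z_nm", "dx_nm", "dy_nm", "d_nm", "ratio")] <- NA_real_
  out
}

#' Calibration diagnostics
#'
#' Summarises fit quality and flags the problems that matter in practice: a
#' non-monotonic angle-versus-frame sequence (the calibration series covers
#' more than 180 degrees, or the bead was lost), a non-monotonic fitted
#' z(theta), and frames whose z residual exceeds 3x the median absolute
#' residual. From the latter a trimmed usable angle range is suggested by
#' peeling flagged frames off both ends of the series.
#'
#' @param model A `dh_calibration` built by [build_calibration()] (the
#'   stored per-frame features are required).
#' @return A list of class `dh_calibration_report`: `curve_rms`,
#'   `theta_monotonic`, `z_monotonic`, `n_flagged`, `flagged_frames`,
#'   `suggested_theta_range`, `suggested_frame_range`, `features`.
#' @seealso [autoplot.dh_calibration()] for the five-curve diagnostic plot,
#'   [save_calibration_diagnostics()] to serialise report and plot.
#' @export
calibration_diagnostics <- function(model) {
  stopifnot(inherits(model, "dh_calibration"))
  feats <- model$features
  if (is.null(feats)) abort("model carries no stored features (was it loaded from file?); rebuild with build_calibration().")
  resid <- feats$z_nm - cheb_eval(model$curves$z, feats$theta_deg)
  thr <- 3 * max(median(abs(resid)), .Machine$double.eps)
  flagged <- abs(resid) > thr
  ok <- which(!flagged)
  lo <- if (length(ok) > 0) min(ok) else NA_integer_
  hi <- if (length(ok) > 0) max(ok) else NA_integer_
  dtheta <- diff(feats$theta_deg)
  zg <- cheb_eval(model$curves$z,
                  seq(model$theta_range[1], model$theta_range[2], length.out = 1000))
  structure(
    list(
      curve_rms = model$residual_rms,
      theta_monotonic = all(dtheta > 0) || all(dtheta < 0),
      z_monotonic = all(diff(zg) > 0) || all(diff(zg) < 0),
      n_flagged = sum(flagged),
      flagged_frames = feats$frame[flagged],
      suggested_theta_range = if (!is.na(lo)) sort(feats$theta_deg[c(lo, hi)]) else c(NA_real_, NA_real_),
      suggested_frame_range = if (!is.na(lo)) c(feats$frame[lo], feats$frame[hi]) else c(NA_integer_, NA_integer_),
      features = feats
    ),
    class = "dh_calibration_report"
  )
}

#' @export
print.dh_calibration_report <- function(x, ...) {
  cat("<dh_calibration_report>\n")
  cat(sprintf("  residual RMS: z %.3g nm, d %.3g nm, ratio %.3g\n",
              x$curve_rms[["z"]], x$curve_rms[["d"]], x$curve_rms[["r"]]))
  cat(sprintf("  angle monotonic with frame: %s; fitted z monotonic: %s\n",
              x$theta_monotonic, x$z_monotonic))
  cat(sprintf("  %d frame(s) with |z residual| > 3 x median: %s\n",
              x$n_flagged,
              if (x$n_flagged > 0) paste(x$flagged_frames, collapse = ", ") else "-"))
  cat(sprintf("  suggested angle range: [%.2f, %.2f] deg (frames %s..%s)\n",
              x$suggested_theta_range[1], x$suggested_theta_range[2],
              x$suggested_frame_range[1], x$suggested_frame_range[2]))
  invisible(x)
}

#' Plot the five calibration curves with their polynomial fits
#'
#' One panel per curve (z, midpoint shift dx and dy, interlobe distance,
#' intensity ratio) against the rotation angle: measured per-frame values as
#' points, fitted polynomial as a line.
#'
#' @param object A `dh_calibration` with stored features.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot dh_calibration
#' @export
autoplot.dh_calibration <- function(object, ...) {
  feats <- object$features
  if (is.null(feats)) abort("model carries no stored features; rebuild with build_calibration().")
  long <- tidyr::pivot_longer(
    feats[c("theta_deg", "z_nm", "dx_nm", "dy_nm", "d_nm", "ratio")],
    -"theta_deg", names_to = "curve", values_to = "value"
  )
  grid <- seq(object$theta_range[1], object$theta_range[2], length.out = 400)
  fit <- tibble(
    theta_deg = rep(grid, 5),
    curve = rep(c("z_nm", "dx_nm", "dy_nm", "d_nm", "ratio"), each = length(grid)),
    value = c(cheb_eval(object$curves$z, grid), cheb_eval(object$curves$dx, grid),
              cheb_eval(object$curves$dy, grid), cheb_eval(object$curves$d, grid),
              cheb_eval(object$curves$r, grid))
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$theta_deg, y = .data$value)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.6) +
    ggplot2::geom_line(data = fit, colour = "orange") +
    ggplot2::facet_wrap(~curve, scales = "free_y") +
    ggplot2::labs(x = "rotation angle (deg)", y = NULL,
                  title = "Calibration curves and polynomial fits")
}

#' Serialise a diagnostic report to text and PNG
#'
#' @param model A `dh_calibration` with stored features.
#' @param dir Output directory (created if needed).
#' @return Paths of the written files, invisibly.
#' @export
save_calibration_diagnostics <- function(model, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  report <- calibration_diagnostics(model)
  txt <- file.path(dir, "calibration_diagnostics.txt")
  png <- file.path(dir, "calibration_curves.png")
  writeLines(utils::capture.output(print(report)), txt)
  ggplot2::ggsave(png, autoplot(model), width = 8, height = 5, dpi = 120)
  invisible(c(txt, png))
}

#' @method tidy dh_calibration
#' @export
tidy.dh_calibration <- function(x, ...) {
  bind_rows(lapply(names(x$curves), function(nm) {
    tibble(curve = nm, order = seq_along(x$curves[[nm]]$coef) - 1L,
           coefficient = x$curves[[nm]]$coef)
  }))
}

#' @method glance dh_calibration
#' @export
glance.dh_calibration <- function(x, ...) {
  tibble(
    degree = x$degree,
    theta_lo = x$theta_range[1], theta_hi = x$theta_range[2],
    n_frames = x$n_frames_used %||% NA_integer_,
    rms_z_nm = unname(x$residual_rms["z"]),
    rms_d_nm = unname(x$residual_rms["d"]),
    rms_ratio = unname(x$residual_rms["r"]),
    rms_dx_nm = unname(x$residual_rms["dx"]),
    rms_dy_nm = unname(x$residual_rms["dy"])
  )
}
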