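#' Parametric rotating two-lobe PSF generator
#'
#' Defines the forward model used by the simulator: over the axial range the
#' two lobes rotate linearly with z (total rotation strictly below 180 degrees
#' so the angle-to-z mapping stays unambiguous), the interlobe distance grows
#' quadratically away from focus, the lobe intensity ratio varies linearly
#' with z, and the lobe midpoint wobbles laterally following smooth sinusoidal
#' laws. Each lobe is rendered as a pixel-integrated 2D Gaussian.
#'
#' Defaults mimic a commercial DH-PSF system with a 210 nm camera pixel and a
#' roughly 4 um usable axial range: 170 degrees of rotation over
#' z in (-2000, 2000) nm, a 1050 nm in-focus interlobe distance growing by 25%
#' at the range extremes, intensity ratio spanning 0.75-1.25, and a few tens
#' of nm of wobble.
#'
#' @param pixel_size_nm Lateral camera pixel size in nm.
#' @param sigma_px Gaussian width of each lobe, in pixels.
#' @param theta0_deg Rotation angle at the low end of the axial range, degrees.
#' @param theta_span_deg Total rotation over the axial range; must be in
#'   (0, 180) to keep the angle-to-z correspondence unique.
#' @param z_range_nm Length-2 numeric, axial range (z_min, z_max) in nm.
#' @param d0_nm Interlobe distance at z = 0, nm.
#' @param d2_nm Quadratic coefficient of the distance law
#'   `d(z) = d0 + d2 * z^2` (nm^-1). Default grows d by 25% at the range
#'   extremes.
#' @param ratio_slope Linear coefficient of the intensity-ratio law
#'   `r(z) = 1 + ratio_slope * z` (per nm).
#' @param wobble_amp_nm Length-2 amplitudes (ax, ay) of the sinusoidal
#'   midpoint wobble, nm. Both laws are zero at z_min so the first calibration
#'   frame is the natural wobble reference.
#' @param flux Total photon flux (arbitrary camera counts) of one molecule
#'   before the per-molecule intensity factor.
#' @param canvas_px Length-2 integer, default (width, height) of simulated
#'   frames in pixels.
#'
#' @return An object of class `dh_generator`.
#' @seealso [psf_truth()], [simulate_calibration()], [simulate_dataset()]
#' @export
dh_generator <- function(pixel_size_nm = 210,
                         sigma_px = 1.1,
                         theta0_deg = 5,
                         theta_span_deg = 170,
                         z_range_nm = c(-2000, 2000),
                         d0_nm = 1050,
                         d2_nm = NULL,
                         ratio_slope = 1.25e-4,
                         wobble_amp_nm = c(40, 30),
                         flux = 5000,
                         canvas_px = c(256, 256)) {
  assert_number(pixel_size_nm, "pixel_size_nm", positive = TRUE)
  assert_number(sigma_px, "sigma_px", positive = TRUE)
  assert_number(theta_span_deg, "theta_span_deg")
  if (theta_span_deg <= 0 || theta_span_deg >= 180) {
    abort("`theta_span_deg` must lie in (0, 180): a rotation of 180 degrees or more makes the angle-to-z mapping ambiguous.")
  }
  if (length(z_range_nm) != 2L || diff(z_range_nm) <= 0) {
    abort("`z_range_nm` must be (z_min, z_max) with z_min < z_max.")
  }
  d2_nm <- d2_nm %||% (0.25 * d0_nm / max(abs(z_range_nm))^2)
  gen <- structure(
    list(
      pixel_size_nm = pixel_size_nm,
      sigma_px = sigma_px,
      theta0_deg = theta0_deg,
      theta_span_deg = theta_span_deg,
      z_range_nm = as.numeric(z_range_nm),
      d0_nm = d0_nm,
      d2_nm = d2_nm,
      ratio_slope = ratio_slope,
      wobble_amp_nm = as.numeric(wobble_amp_nm),
      flux = flux,
      canvas_px = as.integer(canvas_px)
    ),
    class = "dh_generator"
  )
  # distance and ratio laws must stay positive over the whole range
  zz <- seq(z_range_nm[1], z_range_nm[2], length.out = 101)
  if (any(gen$d0_nm + gen$d2_nm * zz^2 <= 0)) abort("distance law d(z) must be > 0 on the axial range.")
  if (any(1 + gen$ratio_slope * zz <= 0)) abort("ratio law r(z) must be > 0 on the axial range.")
  gen
}

#' @export
print.dh_generator <- function(x, ...) {
  cat("<dh_generator>\n")
  cat(sprintf("  pixel %g nm, lobe sigma %g px, canvas %d x %d px\n",
              x$pixel_size_nm, x$sigma_px, x$canvas_px[1], x$canvas_px[2]))
  cat(sprintf("  z range [%g, %g] nm; theta %g -> %g deg\n",
              x$z_range_nm[1], x$z_range_nm[2],
              x$theta0_deg, x$theta0_deg + x$theta_span_deg))
  cat(sprintf("  d(z) = %g + %.3g z^2 nm; r(z) = 1 + %.3g z; wobble (%g, %g) nm\n",
              x$d0_nm, x$d2_nm, x$ratio_slope,
              x$wobble_amp_nm[1], x$wobble_amp_nm[2]))
  invisible(x)
}

#' Evaluate the generator's ground-truth PSF feature laws
#'
#' Returns, for each axial position, the rotation angle, interlobe distance,
#' lobe intensity ratio and midpoint wobble that the generator renders. These
#' are the exact curves a calibration fit must recover.
#'
#' The angle law is linear,
#' `theta(z) = theta0 + theta_span * (z - z_min) / (z_max - z_min)`,
#' folded into \[0, 180). The ratio follows the lobe-ordering convention used
#' throughout the package: intensity of the lobe with smaller x (ties broken
#' by smaller y) divided by the other lobe.
#'
#' @param z_nm Numeric vector of axial positions (nm); must lie within the
#'   generator's `z_range_nm`.
#' @param gen A [dh_generator()].
#' @return A tibble with columns `z_nm`, `theta_deg`, `d_nm`, `ratio`,
#'   `wobble_x_nm`, `wobble_y_nm`.
#' @export
psf_truth <- function(z_nm, gen) {
  stopifnot(inherits(gen, "dh_generator"))
  zr <- gen$z_range_nm
  if (any(z_nm < zr[1] - 1e-9 | z_nm > zr[2] + 1e-9)) {
    abort("`z_nm` outside the generator's axial range.")
  }
  span_z <- zr[2] - zr[1]
  u <- (z_nm - zr[1]) / span_z
  tibble(
    z_nm = z_nm,
    theta_deg = fold_angle_deg(gen$theta0_deg + gen$theta_span_deg * u),
    d_nm = gen$d0_nm + gen$d2_nm * z_nm^2,
    ratio = 1 + gen$ratio_slope * z_nm,
    wobble_x_nm = gen$wobble_amp_nm[1] * sin(pi * u),
    wobble_y_nm = gen$wobble_amp_nm[2] * sin(2 * pi * u)
  )
}

# Lobe centres (pixel coordinates, 0-based) and per-lobe fluxes for one
# molecule. Truth (x_nm, y_nm) is the pre-wobble midpoint; the rendered
# midpoint is shifted by the wobble law. The generator ratio r applies to the
# smaller-x (tie: smaller-y) lobe over the other, matching pair_features().
lobe_geometry <- function(x_nm, y_nm, z_nm, intensity, gen) {
  pt <- psf_truth(z_nm, gen)
  px <- gen$pixel_size_nm
  th <- pt$theta_deg * pi / 180
  mx <- (x_nm + pt$wobble_x_nm) / px
  my <- (y_nm + pt$wobble_y_nm) / px
  hx <- (pt$d_nm / 2 / px) * cos(th)
  hy <- (pt$d_nm / 2 / px) * sin(th)
  c1x <- mx + hx; c1y <- my + hy
  c2x <- mx - hx; c2y <- my - hy
  # which lobe is "A" (smaller x, ties smaller y)?
  a_is_1 <- (c1x < c2x) | (c1x == c2x & c1y <= c2y)
  fa <- intensity * pt$ratio / (1 + pt$ratio)
  fb <- intensity / (1 + pt$ratio)
  list(
    ax = ifelse(a_is_1, c1x, c2x), ay = ifelse(a_is_1, c1y, c2y),
    bx = ifelse(a_is_1, c2x, c1x), by = ifelse(a_is_1, c2y, c1y),
    flux_a = fa, flux_b = fb, truth = pt
  )
}
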