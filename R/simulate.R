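# Simulator: renders rotating two-lobe PSFs onto count canvases and builds
# calibration stacks and benchmark datasets with known ground truth.

# Add one pixel-integrated 2D Gaussian lobe to `canvas` (matrix, row = y,
# col = x, 0-based pixel coordinates). Returns the updated canvas. The lobe
# is rendered on a +/- 6 sigma window; flux outside that window (<1e-8 of
# the total) is ignored.
add_lobe <- function(canvas, cx, cy, flux, sigma) {
  h <- nrow(canvas); w <- ncol(canvas)
  r <- ceiling(6 * sigma)
  jlo <- max(0L, floor(cx) - r); jhi <- min(w - 1L, ceiling(cx) + r)
  ilo <- max(0L, floor(cy) - r); ihi <- min(h - 1L, ceiling(cy) + r)
  if (jlo > jhi || ilo > ihi) return(canvas)
  js <- jlo:jhi; is <- ilo:ihi
  gx <- pnorm((js + 0.5 - cx) / sigma) - pnorm((js - 0.5 - cx) / sigma)
  gy <- pnorm((is + 0.5 - cy) / sigma) - pnorm((is - 0.5 - cy) / sigma)
  canvas[is + 1L, js + 1L] <- canvas[is + 1L, js + 1L] + flux * outer(gy, gx)
  canvas
}

#' Render one molecule's double-helix PSF onto a canvas
#'
#' Places the two lobes at `midpoint +/- (d/2)(cos theta, sin theta)` plus the
#' wobble shift, splits the total flux between the lobes according to the
#' generator's ratio law, and renders each lobe as a pixel-integrated 2D
#' Gaussian. The total added flux equals `intensity` up to the truncation of
#' the rendering window and the canvas borders.
#'
#' @param canvas Numeric matrix (row = y, column = x; 0-based pixel
#'   coordinates, pixel centres at integer coordinates).
#' @param x_nm,y_nm Ground-truth midpoint position (pre-wobble), nm.
#' @param z_nm Axial position, nm; must be inside the generator range.
#' @param intensity Total flux of the molecule (counts).
#' @param gen A [dh_generator()].
#' @return The canvas with the molecule added. If the molecule falls fully
#'   outside the canvas it is skipped with a warning.
#' @export
render_molecule <- function(canvas, x_nm, y_nm, z_nm, intensity, gen) {
  g <- lobe_geometry(x_nm, y_nm, z_nm, intensity, gen)
  h <- nrow(canvas); w <- ncol(canvas)
  r <- 6 * gen$sigma_px
  inside <- function(cx, cy) cx > -r && cx < w - 1 + r && cy > -r && cy < h - 1 + r
  if (!inside(g$ax, g$ay) && !inside(g$bx, g$by)) {
    warn("molecule fully outside the canvas; skipped")
    return(canvas)
  }
  canvas <- add_lobe(canvas, g$ax, g$ay, g$flux_a, gen$sigma_px)
  add_lobe(canvas, g$bx, g$by, g$flux_b, gen$sigma_px)
}

# Brightest rendered pixel of one molecule on an otherwise empty canvas;
# used by the S/N definition (mean brightest pixel / noise sd).
molecule_peak_value <- function(x_nm, y_nm, z_nm, intensity, gen) {
  g <- lobe_geometry(x_nm, y_nm, z_nm, intensity, gen)
  s <- gen$sigma_px
  r <- ceiling(6 * s)
  peak_near <- function(cx, cy) {
    js <- (floor(cx) - 1L):(ceiling(cx) + 1L)
    is <- (floor(cy) - 1L):(ceiling(cy) + 1L)
    val <- function(ox, oy, f) {
      gx <- pnorm((js + 0.5 - ox) / s) - pnorm((js - 0.5 - ox) / s)
      gy <- pnorm((is + 0.5 - oy) / s) - pnorm((is - 0.5 - oy) / s)
      f * outer(gy, gx)
    }
    m <- val(g$ax, g$ay, g$flux_a) + val(g$bx, g$by, g$flux_b)
    max(m)
  }
  max(peak_near(g$ax, g$ay), peak_near(g$bx, g$by))
}

#' Simulate a calibration z-stack of a single bead
#'
#' One frame per axial step, bead at the canvas centre, starting at the low
#' end of the generator's axial range. Defaults follow the common acquisition
#' scheme of 119 positions with a 33.3 nm axial step, spanning close to the
#' full 4 um range of the DH-PSF.
#'
#' @param gen A [dh_generator()].
#' @param n_steps Number of axial positions (frames).
#' @param step_nm Axial step between frames, nm.
#' @param canvas_px Frame size (width, height) in pixels.
#' @param noise_sd Optional Gaussian noise sd added to each frame (counts).
#' @param background Constant background level (counts).
#' @param seed Optional RNG seed (only used when `noise_sd > 0`).
#' @return A list with `stack` (a [dh_stack()]), `z_nm` (per-frame axial
#'   positions) and `truth` (tibble of the bead position per frame).
#' @export
simulate_calibration <- function(gen, n_steps = 119, step_nm = 33.3,
                                 canvas_px = c(40, 40), noise_sd = 0,
                                 background = 0, seed = NULL) {
  stopifnot(inherits(gen, "dh_generator"))
  z <- gen$z_range_nm[1] + (seq_len(n_steps) - 1L) * step_nm
  if (max(z) > gen$z_range_nm[2] + 1e-9) {
    abort("n_steps * step_nm exceeds the generator's axial range.")
  }
  if (!is.null(seed)) set.seed(seed)
  w <- canvas_px[1]; h <- canvas_px[2]
  cx_nm <- (w - 1) / 2 * gen$pixel_size_nm
  cy_nm <- (h - 1) / 2 * gen$pixel_size_nm
  frames <- vector("list", n_steps)
  for (i in seq_len(n_steps)) {
    f <- matrix(background, h, w)
    f <- render_molecule(f, cx_nm, cy_nm, z[i], gen$flux, gen)
    if (noise_sd > 0) f <- f + matrix(rnorm(h * w, 0, noise_sd), h, w)
    frames[[i]] <- f
  }
  list(
    stack = dh_stack(frames, gen$pixel_size_nm),
    z_nm = z,
    truth = tibble(frame = seq_len(n_steps) - 1L, x_nm = cx_nm, y_nm = cy_nm, z_nm = z)
  )
}

#' Simulate a multi-frame benchmark dataset with known ground truth
#'
#' Molecules are placed uniformly over the canvas interior with sub-pixel
#' precision (a border margin keeps whole PSFs inside the frame), axial
#' positions are uniform over `z_window_nm`, and each molecule's flux is
#' scaled by an intensity factor drawn from U(1, 1.2). Pixelwise Gaussian
#' noise is added on a constant background of level 50 (counts). The noise
#' standard deviation is solved from the requested signal-to-noise ratio,
#' defined as the mean brightest rendered pixel across molecules divided by
#' the noise standard deviation.
#'
#' @param gen A [dh_generator()].
#' @param n_frames Number of frames.
#' @param per_frame Number of molecules per frame (the localisation density).
#' @param snr_target Target signal-to-noise ratio (see Details).
#' @param seed RNG seed; the same seed reproduces the stack bit for bit.
#' @param canvas_px Frame size (width, height) in pixels; default from `gen`.
#' @param z_window_nm Axial window molecules are drawn from; default the full
#'   generator range.
#' @param background_mean Mean background level, counts.
#' @return A list with `stack` (a [dh_stack()], floating-point counts) and
#'   `scene` (class `dh_scene`): ground-truth tibble `truth` with columns
#'   `frame`, `x_nm`, `y_nm`, `z_nm`, `intensity_factor`, `flux`,
#'   `peak_value`, the generator parameters, the solved `noise_sd` and the
#'   achieved S/N.
#' @export
simulate_dataset <- function(gen, n_frames, per_frame, snr_target,
                             seed = NULL, canvas_px = gen$canvas_px,
                             z_window_nm = gen$z_range_nm,
                             background_mean = 50) {
  stopifnot(inherits(gen, "dh_generator"))
  if (per_frame <= 0) abort("`per_frame` must be >= 1.")
  assert_number(snr_target, "snr_target", positive = TRUE)
  if (!is.null(seed)) set.seed(seed)
  w <- canvas_px[1]; h <- canvas_px[2]
  px <- gen$pixel_size_nm

  # border margin: whole PSF (half interlobe distance + wobble + 3 sigma)
  # stays inside the frame, mirroring border exclusion during evaluation
  d_max <- max(psf_truth(seq(z_window_nm[1], z_window_nm[2], length.out = 201), gen)$d_nm)
  margin_px <- 3 * gen$sigma_px + (d_max / 2 + max(abs(gen$wobble_amp_nm))) / px
  if (2 * margin_px >= min(w, h) - 1) abort("canvas too small for the PSF extent.")

  n <- n_frames * per_frame
  truth <- tibble(
    frame = rep(seq_len(n_frames) - 1L, each = per_frame),
    x_nm = runif(n, margin_px, (w - 1) - margin_px) * px,
    y_nm = runif(n, margin_px, (h - 1) - margin_px) * px,
    z_nm = runif(n, z_window_nm[1], z_window_nm[2]),
    intensity_factor = runif(n, 1, 1.2)
  )
  truth$flux <- gen$flux * truth$intensity_factor
  truth$peak_value <- vapply(
    seq_len(n),
    function(i) molecule_peak_value(truth$x_nm[i], truth$y_nm[i], truth$z_nm[i],
                                    truth$flux[i], gen),
    numeric(1)
  )
  noise_sd <- mean(truth$peak_value) / snr_target

  frames <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    canvas <- matrix(0, h, w)
    rows <- which(truth$frame == f - 1L)
    for (i in rows) {
      canvas <- render_molecule(canvas, truth$x_nm[i], truth$y_nm[i],
                                truth$z_nm[i], truth$flux[i], gen)
    }
    frames[[f]] <- canvas + background_mean + matrix(rnorm(h * w, 0, noise_sd), h, w)
  }

  scene <- structure(
    list(
      truth = truth,
      params = list(
        n_frames = n_frames, per_frame = per_frame, snr_target = snr_target,
        seed = seed, canvas_px = c(w, h), z_window_nm = as.numeric(z_window_nm),
        background_mean = background_mean, generator = gen
      ),
      noise_sd = noise_sd,
      achieved_snr = mean(truth$peak_value) / noise_sd
    ),
    class = "dh_scene"
  )
  list(stack = dh_stack(frames, px), scene = scene)
}

#' @export
print.dh_scene <- function(x, ...) {
  cat("<dh_scene>\n")
  cat(sprintf("  %d frames x %d molecules/frame; S/N %.2f (noise sd %.2f)\n",
              x$params$n_frames, x$params$per_frame, x$achieved_snr, x$noise_sd))
  cat(sprintf("  canvas %d x %d px; z window [%g, %g] nm; seed %s\n",
              x$params$canvas_px[1], x$params$canvas_px[2],
              x$params$z_window_nm[1], x$params$z_window_nm[2],
              x$params$seed %||% "none"))
  invisible(x)
}

#' Estimate the achieved signal-to-noise ratio of a simulated stack
#'
#' Applies the S/N definition (mean brightest pixel across localisations
#' divided by the noise standard deviation) directly to the noisy stack:
#' for each ground-truth molecule the pixel value at its predicted brightest
#' pixel is read off the rendered frame, the per-frame background (median) is
#' subtracted, and a robust noise sd is estimated from the median absolute
#' deviation of the frames.
#'
#' @param stack A [dh_stack()] produced by [simulate_dataset()].
#' @param scene The matching `dh_scene`.
#' @return A single number, the measured S/N.
#' @export
estimate_snr <- function(stack, scene) {
  stopifnot(inherits(stack, "dh_stack"), inherits(scene, "dh_scene"))
  gen <- scene$params$generator
  truth <- scene$truth
  s <- gen$sigma_px
  vals <- numeric(nrow(truth))
  bgs <- vapply(stack$frames, median, numeric(1))
  sds <- vapply(stack$frames, mad, numeric(1))
  for (i in seq_len(nrow(truth))) {
    g <- lobe_geometry(truth$x_nm[i], truth$y_nm[i], truth$z_nm[i], truth$flux[i], gen)
    # predicted brightest pixel: search 3x3 around the brighter lobe centre
    cx <- if (g$flux_a >= g$flux_b) g$ax else g$bx
    cy <- if (g$flux_a >= g$flux_b) g$ay else g$by
    fr <- stack$frames[[truth$frame[i] + 1L]]
    js <- pmax(0L, pmin(ncol(fr) - 1L, (round(cx) - 1L):(round(cx) + 1L)))
    is <- pmax(0L, pmin(nrow(fr) - 1L, (round(cy) - 1L):(round(cy) + 1L)))
    gx <- pnorm((js + 0.5 - g$ax) / s) - pnorm((js - 0.5 - g$ax) / s)
    gy <- pnorm((is + 0.5 - g$ay) / s) - pnorm((is - 0.5 - g$ay) / s)
    m <- g$flux_a * outer(gy, gx)
    gx2 <- pnorm((js + 0.5 - g$bx) / s) - pnorm((js - 0.5 - g$bx) / s)
    gy2 <- pnorm((is + 0.5 - g$by) / s) - pnorm((is - 0.5 - g$by) / s)
    m <- m + g$flux_b * outer(gy2, gx2)
    idx <- which(m == max(m), arr.ind = TRUE)[1, ]
    vals[i] <- fr[is[idx[1]] + 1L, js[idx[2]] + 1L] - bgs[truth$frame[i] + 1L]
  }
  mean(vals) / median(sds)
}
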