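# Spot detection: Gaussian-smoothed local-maximum candidate finding followed
# by pixel-integrated 2D Gaussian least-squares fitting of each lobe.

#' Detection parameters
#'
#' @param smoothing_sigma_px Sigma of the Gaussian smoothing applied before
#'   candidate finding, in pixels. Also used as the width prior / initial
#'   value of the Gaussian fit; set it to the expected lobe sigma (a matched
#'   filter).
#' @param threshold Candidate threshold as a multiple of the robust noise sd
#'   of the smoothed frame, above its median background.
#' @param fit_window_px Side of the square fit window (odd, >= 5).
#' @param max_iterations Cap on Levenberg-Marquardt iterations per fit.
#' @param min_separation_px Candidate maxima closer than this keep only the
#'   brighter one.
#' @return A list of class `dh_detection_params`.
#' @export
detection_params <- function(smoothing_sigma_px = 1.1, threshold = 4,
                             fit_window_px = 9, max_iterations = 60,
                             min_separation_px = 2) {
  if (fit_window_px < 5 || fit_window_px %% 2 == 0) {
    abort("`fit_window_px` must be an odd integer >= 5.")
  }
  if (threshold <= 0) abort("`threshold` must be > 0.")
  structure(
    list(smoothing_sigma_px = smoothing_sigma_px, threshold = threshold,
         fit_window_px = as.integer(fit_window_px),
         max_iterations = as.integer(max_iterations),
         min_separation_px = min_separation_px),
    class = "dh_detection_params"
  )
}

# cache of banded smoothing matrices, keyed by "n:sigma"
.smoother_cache <- new.env(parent = emptyenv())

smoother_matrix <- function(n, sigma) {
  key <- paste0(n, ":", sigma)
  if (!is.null(.smoother_cache[[key]])) return(.smoother_cache[[key]])
  m <- ceiling(4 * sigma)
  off <- -m:m
  g <- dnorm(off, sd = sigma)
  K <- matrix(0, n, n)
  for (k in seq_along(off)) {
    idx <- seq_len(n)
    j <- idx + off[k]
    ok <- j >= 1 & j <= n
    K[cbind(idx[ok], j[ok])] <- g[k]
  }
  K <- K / rowSums(K)  # renormalise truncated edge rows
  .smoother_cache[[key]] <- K
  K
}

# separable Gaussian smoothing via two banded matrix products
gauss_smooth <- function(frame, sigma) {
  Ky <- smoother_matrix(nrow(frame), sigma)
  Kx <- smoother_matrix(ncol(frame), sigma)
  Ky %*% frame %*% t(Kx)
}

#' Find candidate lobes in one frame
#'
#' Candidates are local maxima of the Gaussian-smoothed frame exceeding the
#' smoothed frame's median background plus `threshold` times its robust noise
#' sd (1.4826 x MAD). Maxima closer than `min_separation_px` keep only the
#' brighter.
#'
#' @param frame Numeric matrix (row = y, column = x).
#' @param params A [detection_params()].
#' @return A tibble with integer 0-based columns `x_px`, `y_px` and the
#'   smoothed `value`; zero rows when nothing exceeds the threshold.
#' @export
find_candidates <- function(frame, params = detection_params()) {
  sm <- gauss_smooth(frame, params$smoothing_sigma_px)
  # epsilon keeps numerically flat frames from promoting rounding noise
  thr <- median(sm) + params$threshold * mad(sm) + 1e-9 * (abs(median(sm)) + 1)
  h <- nrow(sm); w <- ncol(sm)
  if (h < 3 || w < 3) return(tibble(x_px = integer(), y_px = integer(), value = numeric()))
  ci <- 2:(h - 1); cj <- 2:(w - 1)
  centre <- sm[ci, cj]
  # strict > for half the neighbours, >= for the other half: plateau ties
  # yield exactly one maximum
  is_max <- centre > thr &
    centre >  sm[ci - 1, cj]     & centre >  sm[ci - 1, cj - 1] &
    centre >  sm[ci,     cj - 1] & centre >  sm[ci + 1, cj - 1] &
    centre >= sm[ci + 1, cj]     & centre >= sm[ci + 1, cj + 1] &
    centre >= sm[ci,     cj + 1] & centre >= sm[ci - 1, cj + 1]
  idx <- which(is_max, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(tibble(x_px = integer(), y_px = integer(), value = numeric()))
  cand <- tibble(
    x_px = as.integer(idx[, 2] + 1L - 1L),  # back to full-frame col, 0-based
    y_px = as.integer(idx[, 1] + 1L - 1L),
    value = centre[idx]
  )
  cand <- cand[order(-cand$value, cand$y_px, cand$x_px), ]
  if (nrow(cand) > 1L) {
    keep <- logical(nrow(cand))
    kx <- numeric(0); ky <- numeric(0)
    for (k in seq_len(nrow(cand))) {
      if (length(kx) == 0L ||
          all((kx - cand$x_px[k])^2 + (ky - cand$y_px[k])^2 >= params$min_separation_px^2)) {
        keep[k] <- TRUE
        kx <- c(kx, cand$x_px[k]); ky <- c(ky, cand$y_px[k])
      }
    }
    cand <- cand[keep, ]
  }
  cand
}

#' Fit one spot as a pixel-integrated 2D Gaussian
#'
#' Least-squares fit of centre, total flux, width and constant offset on a
#' square window around the candidate, by damped Gauss-Newton
#' (Levenberg-Marquardt) with an analytic Jacobian. The model value of pixel
#' (i, j) is `b + F * [Phi((j+.5-x0)/s) - Phi((j-.5-x0)/s)] *
#' [Phi((i+.5-y0)/s) - Phi((i-.5-y0)/s)]`, so `F` is directly the
#' background-subtracted integrated intensity.
#'
#' When the centres of other candidates in the frame are supplied, pixels of
#' the window that lie closer to another candidate than to this one are
#' excluded from the fit (a Voronoi mask), so a neighbouring lobe does not
#' bias the centre, flux or background estimates.
#'
#' @param frame Numeric matrix.
#' @param x_px,y_px Integer candidate position (0-based).
#' @param params A [detection_params()].
#' @param others Optional 2-column matrix (x_px, y_px) of the other
#'   candidate centres in the frame, for the Voronoi mask.
#' @return A list: `ok` (logical), and either `peak` (one-row tibble with
#'   `x_px`, `y_px`, `intensity`, `sigma_px`, `background`) or `reason`
#'   (one of `"border"`, `"no_convergence"`, `"amplitude"`, `"sigma_range"`,
#'   `"drift"`).
#' @export
fit_spot <- function(frame, x_px, y_px, params = detection_params(), others = NULL) {
  h <- nrow(frame); w <- ncol(frame)
  half <- (params$fit_window_px - 1L) %/% 2L
  if (x_px - half < 0 || x_px + half > w - 1 || y_px - half < 0 || y_px + half > h - 1) {
    return(list(ok = FALSE, reason = "border"))
  }
  js0 <- (x_px - half):(x_px + half)
  is0 <- (y_px - half):(y_px + half)
  win <- frame[is0 + 1L, js0 + 1L]
  jj <- rep(js0, each = length(is0))
  ii <- rep(is0, times = length(js0))
  yv <- as.vector(win)

  keep <- rep(TRUE, length(yv))
  if (!is.null(others) && nrow(others) > 0) {
    d_own <- (jj - x_px)^2 + (ii - y_px)^2
    for (k in seq_len(nrow(others))) {
      keep <- keep & d_own <= (jj - others[k, 1])^2 + (ii - others[k, 2])^2
    }
    if (sum(keep) < 12L) keep <- rep(TRUE, length(yv))
    jj <- jj[keep]; ii <- ii[keep]; yv <- yv[keep]
  }
  sprior <- params$smoothing_sigma_px

  edge <- jj == min(js0) | jj == max(js0) | ii == min(is0) | ii == max(is0)
  ring <- yv[edge]
  b <- if (length(ring) > 0) median(ring) else median(yv)
  Fv <- max(sum(yv - b), max(yv) - b, 1e-6)
  wpos <- pmax(yv - b, 0)
  core <- (jj - x_px)^2 + (ii - y_px)^2 <= (2 * sprior + 1)^2
  tot <- sum(wpos[core])
  x0 <- if (tot > 0) sum(wpos[core] * jj[core]) / tot else x_px
  y0 <- if (tot > 0) sum(wpos[core] * ii[core]) / tot else y_px
  s <- sprior

  lambda <- 1e-3
  sse <- Inf
  converged <- FALSE
  for (iter in seq_len(params$max_iterations)) {
    ax_hi <- (jj + 0.5 - x0) / s; ax_lo <- (jj - 0.5 - x0) / s
    ay_hi <- (ii + 0.5 - y0) / s; ay_lo <- (ii - 0.5 - y0) / s
    gx <- pnorm(ax_hi) - pnorm(ax_lo)
    gy <- pnorm(ay_hi) - pnorm(ay_lo)
    dgx_dx0 <- (dnorm(ax_lo) - dnorm(ax_hi)) / s
    dgy_dy0 <- (dnorm(ay_lo) - dnorm(ay_hi)) / s
    dgx_ds <- (ax_lo * dnorm(ax_lo) - ax_hi * dnorm(ax_hi)) / s
    dgy_ds <- (ay_lo * dnorm(ay_lo) - ay_hi * dnorm(ay_hi)) / s

    G <- gx * gy
    r <- yv - (b + Fv * G)
    sse_now <- sum(r * r)

    J <- cbind(
      Fv * dgx_dx0 * gy,
      Fv * gx * dgy_dy0,
      G,
      Fv * (dgx_ds * gy + gx * dgy_ds),
      1
    )
    JtJ <- crossprod(J)
    Jtr <- crossprod(J, r)
    step_ok <- FALSE
    for (try in 1:8) {
      A <- JtJ + lambda * diag(diag(JtJ) + 1e-12)
      delta <- tryCatch(solve(A, Jtr), error = function(e) NULL)
      if (is.null(delta)) { lambda <- lambda * 10; next }
      x0n <- x0 + delta[1]; y0n <- y0 + delta[2]
      Fn <- max(Fv + delta[3], 1e-9)
      sn <- min(max(s + delta[4], 0.2 * sprior), 5 * sprior)
      bn <- b + delta[5]
      gxn <- pnorm((jj + 0.5 - x0n) / sn) - pnorm((jj - 0.5 - x0n) / sn)
      gyn <- pnorm((ii + 0.5 - y0n) / sn) - pnorm((ii - 0.5 - y0n) / sn)
      rn <- yv - (bn + Fn * gxn * gyn)
      if (sum(rn * rn) <= sse_now) {
        x0 <- x0n; y0 <- y0n; Fv <- Fn; s <- sn; b <- bn
        lambda <- max(lambda / 5, 1e-9)
        step_ok <- TRUE
        break
      }
      lambda <- lambda * 5
    }
    if (!step_ok) { converged <- sse_now <= sse + 1e-12; break }
    moved <- max(abs(delta[1]), abs(delta[2]))
    sse <- sse_now
    if (moved < 1e-5 && iter > 1) { converged <- TRUE; break }
  }
  if (!converged && iter >= params$max_iterations) {
    # accept long fits only if the last step was tiny; otherwise reject
    return(list(ok = FALSE, reason = "no_convergence"))
  }
  if (x0 < min(js0) - 0.5 || x0 > max(js0) + 0.5 || y0 < min(is0) - 0.5 || y0 > max(is0) + 0.5) {
    return(list(ok = FALSE, reason = "drift"))
  }
  peak_amp <- Fv * max(pnorm(0.5 / s) - pnorm(-0.5 / s))^2
  if (Fv <= 1e-6 || peak_amp < 1e-6 * max(1, abs(b))) {
    return(list(ok = FALSE, reason = "amplitude"))
  }
  if (s < 0.5 * sprior || s > 3 * sprior) {
    return(list(ok = FALSE, reason = "sigma_range"))
  }
  list(ok = TRUE, peak = tibble(
    x_px = x0, y_px = y0, intensity = Fv, sigma_px = s, background = b
  ))
}

#' Detect and fit all lobes in a stack
#'
#' Runs [find_candidates()] and [fit_spot()] on every frame and concatenates
#' the accepted fits into a peak table. Fits whose centre lands within 1 px
#' of an already-accepted brighter fit in the same frame are dropped
#' (duplicate suppression). Deterministic given identical inputs.
#'
#' @param stack A [dh_stack()].
#' @param params A [detection_params()].
#' @return A tibble with columns `frame` (0-based), `x_px`, `y_px`,
#'   `intensity`, `sigma_px`, `background`, sorted by frame. Rejection
#'   counts by reason are attached as attribute `"rejects"`.
#' @export
detect_stack <- function(stack, params = detection_params()) {
  stopifnot(inherits(stack, "dh_stack"))
  out <- vector("list", stack$n_frames)
  rejects <- c(border = 0L, no_convergence = 0L, amplitude = 0L,
               sigma_range = 0L, drift = 0L, duplicate = 0L)
  for (f in seq_len(stack$n_frames)) {
    frame <- stack$frames[[f]]
    cand <- find_candidates(frame, params)
    if (nrow(cand) == 0L) next
    fits <- vector("list", nrow(cand))
    nfit <- 0L
    cxy <- cbind(cand$x_px, cand$y_px)
    for (k in seq_len(nrow(cand))) {
      res <- fit_spot(frame, cand$x_px[k], cand$y_px[k], params,
                      others = cxy[-k, , drop = FALSE])
      if (res$ok) {
        nfit <- nfit + 1L
        fits[[nfit]] <- res$peak
      } else {
        rejects[res$reason] <- rejects[res$reason] + 1L
      }
    }
    if (nfit == 0L) next
    pk <- bind_rows(fits[seq_len(nfit)])
    pk <- pk[order(-pk$intensity), ]
    keep <- logical(nrow(pk))
    for (k in seq_len(nrow(pk))) {
      if (k == 1L ||
          all((pk$x_px[keep] - pk$x_px[k])^2 + (pk$y_px[keep] - pk$y_px[k])^2 > 1)) {
        keep[k] <- TRUE
      } else {
        rejects["duplicate"] <- rejects["duplicate"] + 1L
      }
    }
    pk <- pk[keep, ]
    pk$frame <- f - 1L
    out[[f]] <- pk
  }
  peaks <- bind_rows(out)
  if (nrow(peaks) == 0L) {
    peaks <- tibble(frame = integer(), x_px = numeric(), y_px = numeric(),
                    intensity = numeric(), sigma_px = numeric(), background = numeric())
  } else {
    peaks <- peaks[c("frame", "x_px", "y_px", "intensity", "sigma_px", "background")]
  }
  attr(peaks, "rejects") <- rejects
  peaks
}
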