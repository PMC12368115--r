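# Post-processing of localisation tables: lateral drift correction
# (cross-correlation of block reconstructions, or a fiducial track),
# blinking / temporal grouping, and Fourier shell correlation resolution.

#' Estimate lateral drift by block cross-correlation
#'
#' Frames are tiled into blocks of `block_frames`; each block's kept
#' localisations are rendered into a 2D histogram image, and the shift of
#' every block relative to the first (reference) block is found at the
#' cross-correlation peak with parabolic sub-bin refinement.
#'
#' @param locs Localisation tibble (kept rows are used).
#' @param block_frames Number of frames per block.
#' @param bin_nm Histogram bin size, nm; sets the quantisation of the
#'   recovered shifts.
#' @return An object of class `dh_drift`: tibble `trace` with one row per
#'   block (`block`, `frame_start`, `frame_end`, `frame_mid`, `shift_x_nm`,
#'   `shift_y_nm`), plus `bin_nm` and `reference_block = 1`.
#' @export
estimate_drift_xcorr <- function(locs, block_frames, bin_nm = 100) {
  if ("kept" %in% names(locs)) locs <- locs[locs$kept, ]
  if (nrow(locs) == 0L) abort("no kept localisations.")
  f0 <- min(locs$frame)
  f1 <- max(locs$frame)
  n_blocks <- as.integer((f1 - f0) %/% block_frames + 1L)
  if (n_blocks < 2L) {
    trace <- tibble(block = 1L, frame_start = f0, frame_end = f1,
                    frame_mid = (f0 + f1) / 2, shift_x_nm = 0, shift_y_nm = 0)
    return(structure(list(trace = trace, bin_nm = bin_nm, reference_block = 1L),
                     class = "dh_drift"))
  }
  xr <- range(locs$x_nm); yr <- range(locs$y_nm)
  # pad so that drifting structures stay inside the histogram support
  pad <- 10 * bin_nm
  xb <- seq(xr[1] - pad, xr[2] + pad + bin_nm, by = bin_nm)
  yb <- seq(yr[1] - pad, yr[2] + pad + bin_nm, by = bin_nm)
  nx <- length(xb) - 1L; ny <- length(yb) - 1L
  hist2 <- function(sub) {
    ix <- pmin(pmax(findInterval(sub$x_nm, xb), 1L), nx)
    iy <- pmin(pmax(findInterval(sub$y_nm, yb), 1L), ny)
    m <- matrix(0, ny, nx)
    tab <- table(factor(iy, levels = seq_len(ny)), factor(ix, levels = seq_len(nx)))
    m + as.numeric(tab)
  }
  block_of <- as.integer((locs$frame - f0) %/% block_frames) + 1L
  imgs <- lapply(seq_len(n_blocks), function(b) {
    sub <- locs[block_of == b, ]
    if (nrow(sub) == 0L) NULL else hist2(sub)
  })
  P1 <- 2L^ceiling(log2(2L * ny)); P2 <- 2L^ceiling(log2(2L * nx))
  embed <- function(m) {
    out <- matrix(0, P1, P2)
    out[seq_len(ny), seq_len(nx)] <- m
    out
  }
  Fref <- fft(embed(imgs[[1]]))
  shifts <- matrix(0, n_blocks, 2)
  last <- c(0, 0)
  for (b in 2:n_blocks) {
    if (is.null(imgs[[b]])) {
      warn(sprintf("block %d has no localisations; carrying the previous block's shift", b))
      shifts[b, ] <- last
      next
    }
    cc <- Re(fft(fft(embed(imgs[[b]])) * Conj(Fref), inverse = TRUE)) / (P1 * P2)
    pk <- which(cc == max(cc), arr.ind = TRUE)[1, ]
    refine <- function(cm1, c0, cp1) {
      den <- cm1 - 2 * c0 + cp1
      if (den == 0) 0 else 0.5 * (cm1 - cp1) / den
    }
    wrap <- function(i, n) ((i - 1L) %% n) + 1L
    dyi <- pk[1]; dxi <- pk[2]
    sub_y <- refine(cc[wrap(dyi - 1L, P1), dxi], cc[dyi, dxi], cc[wrap(dyi + 1L, P1), dxi])
    sub_x <- refine(cc[dyi, wrap(dxi - 1L, P2)], cc[dyi, dxi], cc[dyi, wrap(dxi + 1L, P2)])
    sy <- dyi - 1L; if (sy > P1 / 2) sy <- sy - P1
    sx <- dxi - 1L; if (sx > P2 / 2) sx <- sx - P2
    shifts[b, ] <- c((sx + sub_x) * bin_nm, (sy + sub_y) * bin_nm)
    last <- shifts[b, ]
  }
  trace <- tibble(
    block = seq_len(n_blocks),
    frame_start = f0 + (seq_len(n_blocks) - 1L) * block_frames,
    frame_end = pmin(f0 + seq_len(n_blocks) * block_frames - 1L, f1),
    shift_x_nm = shifts[, 1], shift_y_nm = shifts[, 2]
  )
  trace$frame_mid <- (trace$frame_start + trace$frame_end) / 2
  structure(list(trace = trace, bin_nm = bin_nm, reference_block = 1L),
            class = "dh_drift")
}

#' @export
print.dh_drift <- function(x, ...) {
  cat(sprintf("<dh_drift> %d block(s), bin %g nm, reference block %d\n",
              nrow(x$trace), x$bin_nm, x$reference_block))
  print(x$trace)
  invisible(x)
}

#' Apply (or revert) a drift trace to a localisation table
#'
#' Block shifts are linearly interpolated at each localisation's frame
#' (constant extrapolation beyond the first/last block midpoints) and
#' subtracted. `direction = "restore"` adds the identical interpolated
#' shifts back, so correct-then-restore is an exact identity.
#'
#' @param locs Localisation tibble.
#' @param drift A `dh_drift` from [estimate_drift_xcorr()].
#' @param direction `"correct"` (subtract drift) or `"restore"` (add back).
#' @return The shifted tibble.
#' @export
apply_drift <- function(locs, drift, direction = c("correct", "restore")) {
  direction <- match.arg(direction)
  stopifnot(inherits(drift, "dh_drift"))
  tr <- drift$trace
  if (nrow(tr) == 1L) return(locs)
  sx <- approx(tr$frame_mid, tr$shift_x_nm, xout = locs$frame, rule = 2)$y
  sy <- approx(tr$frame_mid, tr$shift_y_nm, xout = locs$frame, rule = 2)$y
  sgn <- if (direction == "correct") -1 else 1
  locs$x_nm <- locs$x_nm + sgn * sx
  locs$y_nm <- locs$y_nm + sgn * sy
  locs
}

#' Correct drift using a fiducial marker track
#'
#' Subtracts, from each localisation, the fiducial's displacement from its
#' mean position in the corresponding frame. Gaps in the track are linearly
#' interpolated (and logged); frames beyond the track's ends use the nearest
#' tracked position.
#'
#' @param locs Localisation tibble.
#' @param fiducial_track Tibble with columns `frame`, `x_nm`, `y_nm`.
#' @return The corrected tibble.
#' @export
fiducial_drift <- function(locs, fiducial_track) {
  ft <- fiducial_track[order(fiducial_track$frame), ]
  if (nrow(ft) < 1L) abort("empty fiducial track.")
  if (max(locs$frame) < min(ft$frame) || min(locs$frame) > max(ft$frame)) {
    abort("fiducial track does not overlap the localisation frames.")
  }
  frames_needed <- sort(unique(locs$frame))
  gaps <- setdiff(frames_needed[frames_needed >= min(ft$frame) &
                                  frames_needed <= max(ft$frame)], ft$frame)
  if (length(gaps) > 0) {
    inform(sprintf("fiducial track: interpolating %d missing frame(s)", length(gaps)))
  }
  mx <- mean(ft$x_nm); my <- mean(ft$y_nm)
  if (nrow(ft) == 1L) {
    sx <- rep(ft$x_nm - mx, nrow(locs)); sy <- rep(ft$y_nm - my, nrow(locs))
  } else {
    sx <- approx(ft$frame, ft$x_nm, xout = locs$frame, rule = 2)$y - mx
    sy <- approx(ft$frame, ft$y_nm, xout = locs$frame, rule = 2)$y - my
  }
  locs$x_nm <- locs$x_nm - sx
  locs$y_nm <- locs$y_nm - sy
  locs
}

#' Group localisations from blinking fluorophores
#'
#' Two localisations are linked when their lateral distance is below
#' `dxy_max_nm` (and their axial distance below `dz_max_nm`, if set) and
#' their frames differ by at most `max_gap_frames`. Linking is transitive:
#' each connected component of the link graph becomes one output
#' localisation with unweighted mean coordinates, summed intensity, the
#' first frame, and a multiplicity count.
#'
#' @param locs Localisation tibble; only kept rows are grouped.
#' @param dxy_max_nm Lateral linking distance, nm.
#' @param dz_max_nm Optional axial linking distance, nm.
#' @param max_gap_frames Maximum frame difference between linked
#'   localisations.
#' @param max_extent_nm Optional guard: warn when a grouped component's
#'   lateral extent exceeds this (chained linking can walk further than
#'   `dxy_max_nm`).
#' @return A tibble with `frame` (first), `x_nm`, `y_nm`, `z_nm` (means),
#'   `intensity` (sum), `multiplicity`.
#' @export
group_blinking <- function(locs, dxy_max_nm = 150, dz_max_nm = NULL,
                           max_gap_frames = 50, max_extent_nm = NULL) {
  if ("kept" %in% names(locs)) locs <- locs[locs$kept, ]
  n <- nrow(locs)
  if (n == 0L) {
    return(tibble(frame = integer(), x_nm = numeric(), y_nm = numeric(),
                  z_nm = numeric(), intensity = numeric(), multiplicity = integer()))
  }
  ord <- order(locs$frame)
  locs <- locs[ord, ]
  ei <- integer(0); ej <- integer(0)
  for (i in seq_len(n - 1L)) {
    j <- i + 1L
    js <- j:n
    js <- js[locs$frame[js] - locs$frame[i] <= max_gap_frames]
    if (length(js) == 0L) next
    d2 <- (locs$x_nm[js] - locs$x_nm[i])^2 + (locs$y_nm[js] - locs$y_nm[i])^2
    ok <- d2 < dxy_max_nm^2
    if (!is.null(dz_max_nm)) ok <- ok & abs(locs$z_nm[js] - locs$z_nm[i]) < dz_max_nm
    if (any(ok)) {
      ei <- c(ei, rep(i, sum(ok))); ej <- c(ej, js[ok])
    }
  }
  g <- igraph::graph_from_edgelist(cbind(ei, ej), directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
  comp <- igraph::components(g)$membership[seq_len(n)]
  out <- tibble(comp = comp, frame = locs$frame, x_nm = locs$x_nm,
                y_nm = locs$y_nm, z_nm = locs$z_nm, intensity = locs$intensity) |>
    group_by(.data$comp) |>
    summarise(
      frame = min(.data$frame),
      x_nm = mean(.data$x_nm), y_nm = mean(.data$y_nm), z_nm = mean(.data$z_nm),
      intensity = sum(.data$intensity),
      multiplicity = n(),
      extent = max(0, sqrt((max(.data$x_nm) - min(.data$x_nm))^2 +
                             (max(.data$y_nm) - min(.data$y_nm))^2)),
      .groups = "drop"
    )
  if (!is.null(max_extent_nm) && any(out$extent > max_extent_nm)) {
    warn(sprintf("%d group(s) exceed max_extent_nm = %g nm", sum(out$extent > max_extent_nm), max_extent_nm))
  }
  arrange(select(out, -"comp", -"extent"), .data$frame)
}

#' Fourier shell correlation resolution of a localisation set
#'
#' The kept localisations are randomly split into two half-sets (seeded),
#' each half is voxelised into counts on a common cubic grid, a 3D Gaussian
#' blur is applied, and the correlation between the two half-volumes'
#' Fourier transforms is computed per spherical frequency shell (one
#' frequency bin of the padded cube per shell). The resolution is the
#' inverse of the spatial frequency at the first descent of the curve
#' through the threshold.
#'
#' @param locs Localisation tibble (kept rows used); needs >= 2 rows.
#' @param voxel_nm Voxel size, nm.
#' @param blur_sigma_vox Gaussian blur sigma per axis (x, y, z), voxels.
#' @param threshold FSC threshold; the conventional 1/7 by default.
#' @param seed RNG seed for the random half-split (stored in the result).
#' @param split `"random"` (default) or `"none"`, in which case both halves
#'   are the full set (self-correlation; useful as a sanity check).
#' @return An object of class `dh_fsc`: `curve` (tibble `shell`,
#'   `frequency_nm` in nm^-1, `correlation`, `n_voxels`), `resolution_nm`,
#'   and the parameters used.
#' @export
fsc_resolution <- function(locs, voxel_nm = 5, blur_sigma_vox = c(3, 3, 5),
                           threshold = 1 / 7, seed = NULL,
                           split = c("random", "none")) {
  split <- match.arg(split)
  if ("kept" %in% names(locs)) locs <- locs[locs$kept, ]
  if (nrow(locs) < 2L) abort("need at least 2 localisations for an FSC.")
  xyz <- cbind(locs$x_nm, locs$y_nm, locs$z_nm)
  mins <- apply(xyz, 2, min)
  idx <- floor(sweep(xyz, 2, mins) / voxel_nm)
  ext <- apply(idx, 2, max) + 1L
  pad <- ceiling(3 * max(blur_sigma_vox))
  N <- max(ext) + 2L * pad
  if (N > 512L) abort(sprintf("volume of side %d voxels is too large; increase `voxel_nm`.", N))
  if (!is.null(seed)) set.seed(seed)
  half <- if (split == "random") rbinom(nrow(locs), 1L, 0.5) == 1L else rep(TRUE, nrow(locs))
  voxelise <- function(sel) {
    v <- array(0, dim = c(N, N, N))
    if (!any(sel)) return(v)
    lin <- 1L + (idx[sel, 1] + pad) + N * ((idx[sel, 2] + pad) + N * (idx[sel, 3] + pad))
    tab <- tabulate(lin, nbins = N^3)
    array(tab, dim = c(N, N, N))
  }
  v1 <- voxelise(half)
  v2 <- if (split == "random") voxelise(!half) else v1
  # frequency grids (cycles per voxel) and the Gaussian transfer function;
  # an identical positive real filter on both halves cancels in the
  # correlation, but it is applied for fidelity with the standard pipeline
  k <- 0:(N - 1); k[k > N / 2] <- k[k > N / 2] - N
  f <- k / N
  g1 <- exp(-2 * pi^2 * blur_sigma_vox[1]^2 * f^2)
  g2 <- exp(-2 * pi^2 * blur_sigma_vox[2]^2 * f^2)
  g3 <- exp(-2 * pi^2 * blur_sigma_vox[3]^2 * f^2)
  G <- outer(outer(g1, g2), g3)
  F1 <- fft(v1) * G
  F2 <- if (split == "random") fft(v2) * G else F1
  shell <- array(floor(sqrt(outer(outer(k^2, k^2, "+"), k^2, "+")) + 0.5),
                 dim = c(N, N, N))
  shell_v <- as.integer(shell) + 1L
  num <- rowsum(as.vector(Re(F1 * Conj(F2))), shell_v)
  p1 <- rowsum(as.vector(Mod(F1)^2), shell_v)
  p2 <- rowsum(as.vector(Mod(F2)^2), shell_v)
  cnt <- rowsum(rep(1, length(shell_v)), shell_v)
  smax <- N %/% 2
  sidx <- as.integer(rownames(num))
  keep <- sidx <= smax + 1L
  corr <- as.numeric(num[keep] / sqrt(p1[keep] * p2[keep]))
  corr[!is.finite(corr)] <- 0
  curve <- tibble(
    shell = sidx[keep] - 1L,
    frequency_nm = (sidx[keep] - 1L) / (N * voxel_nm),
    correlation = corr,
    n_voxels = as.integer(cnt[keep])
  )
  curve <- curve[order(curve$shell), ]
  below <- which(curve$correlation < threshold & curve$shell > 0)
  if (length(below) == 0L) {
    resolution <- 2 * voxel_nm  # never drops below threshold: Nyquist-limited
  } else {
    b <- below[1]
    if (b == 1L) {
      resolution <- Inf
    } else {
      f_lo <- curve$frequency_nm[b - 1]; f_hi <- curve$frequency_nm[b]
      c_lo <- curve$correlation[b - 1]; c_hi <- curve$correlation[b]
      fc <- f_lo + (c_lo - threshold) / (c_lo - c_hi) * (f_hi - f_lo)
      resolution <- 1 / fc
    }
  }
  structure(
    list(curve = curve, resolution_nm = resolution, threshold = threshold,
         voxel_nm = voxel_nm, blur_sigma_vox = blur_sigma_vox, seed = seed,
         n_locs = nrow(locs), side_voxels = N),
    class = "dh_fsc"
  )
}

#' @export
print.dh_fsc <- function(x, ...) {
  cat(sprintf("<dh_fsc> %d localisations, %d^3 voxels of %g nm\n",
              x$n_locs, x$side_voxels, x$voxel_nm))
  cat(sprintf("  resolution %.1f nm at threshold %.3f\n", x$resolution_nm, x$threshold))
  invisible(x)
}

#' @rdname fsc_resolution
#' @param object A `dh_fsc`.
#' @param ... Unused.
#' @method autoplot dh_fsc
#' @export
autoplot.dh_fsc <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$frequency_nm, y = .data$correlation)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = object$threshold, linetype = "dashed") +
    ggplot2::geom_vline(xintercept = 1 / object$resolution_nm, colour = "orange") +
    ggplot2::labs(x = expression(spatial ~ frequency ~ (nm^-1)),
                  y = "shell correlation",
                  title = sprintf("FSC resolution %.1f nm", object$resolution_nm))
}

#' Block-wise Fourier shell correlation
#'
#' Splits the localisations into cubic spatial blocks and reports an FSC
#' resolution for every block containing more than `min_locs` localisations,
#' plus their mean. Useful when the resolution varies across a large field.
#'
#' @param locs Localisation tibble.
#' @param block_nm Block side, nm.
#' @param min_locs Minimum localisation count for a block to be analysed.
#' @param seed Base RNG seed; block b uses `seed + b`.
#' @param ... Further arguments passed to [fsc_resolution()].
#' @return A list of class `dh_blockfsc`: `blocks` (tibble with block
#'   indices, localisation counts and per-block resolution),
#'   `mean_resolution_nm`, and `results` (the per-block `dh_fsc` objects).
#'   All-empty input yields zero analysed blocks and `NA` mean.
#' @export
blockwise_fsc <- function(locs, block_nm = 1000, min_locs = 1000, seed = NULL, ...) {
  if ("kept" %in% names(locs)) locs <- locs[locs$kept, ]
  if (nrow(locs) == 0L) {
    return(structure(list(blocks = tibble(bx = integer(), by = integer(), bz = integer(),
                                          n = integer(), resolution_nm = numeric()),
                          mean_resolution_nm = NA_real_, results = list()),
                     class = "dh_blockfsc"))
  }
  bx <- floor(locs$x_nm / block_nm)
  by <- floor(locs$y_nm / block_nm)
  bz <- floor(locs$z_nm / block_nm)
  key <- paste(bx, by, bz)
  occupancy <- tibble(bx = bx, by = by, bz = bz, key = key) |>
    group_by(.data$bx, .data$by, .data$bz, .data$key) |>
    summarise(n = n(), .groups = "drop")
  todo <- occupancy[occupancy$n > min_locs, ]
  results <- list()
  res <- rep(NA_real_, nrow(todo))
  for (b in seq_len(nrow(todo))) {
    sub <- locs[key == todo$key[b], ]
    fsc <- fsc_resolution(sub, seed = if (is.null(seed)) NULL else seed + b, ...)
    results[[todo$key[b]]] <- fsc
    res[b] <- fsc$resolution_nm
  }
  blocks <- select(todo, -"key")
  blocks$resolution_nm <- res
  structure(
    list(blocks = blocks,
         mean_resolution_nm = if (nrow(blocks) > 0) mean(res) else NA_real_,
         results = results, occupancy = select(occupancy, -"key")),
    class = "dh_blockfsc"
  )
}

#' @export
print.dh_blockfsc <- function(x, ...) {
  cat(sprintf("<dh_blockfsc> %d analysed block(s); mean resolution %s nm\n",
              nrow(x$blocks),
              if (is.na(x$mean_resolution_nm)) "NA" else sprintf("%.1f", x$mean_resolution_nm)))
  invisible(x)
}
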