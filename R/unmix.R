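# The pairing core: per frame, lobes are paired through the pairwise
# Euclidean distance matrix, z is assigned from the rotation angle via the
# calibration, midpoints are wobble-corrected, and pairs deviating from the
# calibration's distance or ratio curves are filtered out.

#' Pairing and filtering parameters
#'
#' Tolerances are relative to the calibration curves: a pair is rejected
#' when its interlobe distance deviates from the expected distance at its
#' angle by more than `tol_d` (fractional), or when its intensity ratio
#' deviates from the expected ratio by more than `tol_r` on the log scale
#' (so ratio and inverse-ratio deviations are treated symmetrically).
#'
#' When a calibration model is supplied, the allowed pairing distance range
#' defaults to \[0.8 x min d(theta), 1.2 x max d(theta)\] over the model's
#' usable angle range, anchoring the "expected range" to the calibration
#' instead of hard-coding it.
#'
#' @param model Optional `dh_calibration` used to derive defaults.
#' @param d_min_nm,d_max_nm Allowed pairing distance range, nm.
#' @param tol_d Fractional tolerance on interlobe distance vs calibration.
#' @param tol_r Fractional tolerance on intensity ratio vs calibration.
#' @param pixel_size_nm Pixel size used to convert peak coordinates;
#'   defaults to the model's.
#' @return A list of class `dh_unmix_params`.
#' @export
unmix_params <- function(model = NULL, d_min_nm = NULL, d_max_nm = NULL,
                         tol_d = 0.25, tol_r = 0.25, pixel_size_nm = NULL) {
  if (is.null(d_min_nm) || is.null(d_max_nm) || is.null(pixel_size_nm)) {
    if (is.null(model)) abort("supply either `model` or all of `d_min_nm`, `d_max_nm`, `pixel_size_nm`.")
    grid <- seq(model$theta_range[1], model$theta_range[2], length.out = 512)
    dgrid <- cheb_eval(model$curves$d, grid)
    d_min_nm <- d_min_nm %||% (0.8 * min(dgrid))
    d_max_nm <- d_max_nm %||% (1.2 * max(dgrid))
    pixel_size_nm <- pixel_size_nm %||% model$pixel_size_nm
  }
  if (!(d_min_nm > 0 && d_min_nm < d_max_nm)) abort("need 0 < d_min_nm < d_max_nm.")
  if (tol_d <= 0 || tol_r <= 0) abort("`tol_d` and `tol_r` must be > 0.")
  structure(
    list(d_min_nm = d_min_nm, d_max_nm = d_max_nm, tol_d = tol_d,
         tol_r = tol_r, pixel_size_nm = pixel_size_nm),
    class = "dh_unmix_params"
  )
}

#' Pair the lobes of one frame through the distance matrix
#'
#' All peak pairs whose Euclidean distance lies within
#' \[`d_min_nm`, `d_max_nm`\] are pairing candidates. Conflicts are resolved
#' greedily and deterministically: candidates are processed in ascending
#' order of `|distance - (d_min + d_max)/2|` (ties broken by peak indices)
#' and accepted only if neither peak is already used. Remaining peaks are
#' reported unpaired; lone noise peaks are thereby excluded.
#'
#' @param frame_peaks Peak tibble of a single frame.
#' @param params A [unmix_params()].
#' @return A list: `pairs` (tibble `i`, `j`, `d_nm` of row indices into
#'   `frame_peaks`) and `unpaired` (integer row indices).
#' @export
pair_peaks <- function(frame_peaks, params) {
  n <- nrow(frame_peaks)
  empty <- list(pairs = tibble(i = integer(), j = integer(), d_nm = numeric()),
                unpaired = seq_len(n))
  if (n < 2L) return(empty)
  px <- params$pixel_size_nm
  x <- frame_peaks$x_px * px
  y <- frame_peaks$y_px * px
  dm <- as.matrix(stats::dist(cbind(x, y)))
  idx <- which(upper.tri(dm) & dm >= params$d_min_nm & dm <= params$d_max_nm,
               arr.ind = TRUE)
  if (nrow(idx) == 0L) return(empty)
  d <- dm[idx]
  mid <- (params$d_min_nm + params$d_max_nm) / 2
  ord <- order(abs(d - mid), idx[, 1], idx[, 2])
  used <- logical(n)
  acc <- integer(0)
  for (k in ord) {
    i <- idx[k, 1]; j <- idx[k, 2]
    if (!used[i] && !used[j]) {
      used[i] <- TRUE; used[j] <- TRUE
      acc <- c(acc, k)
    }
  }
  list(
    pairs = tibble(i = as.integer(idx[acc, 1]), j = as.integer(idx[acc, 2]),
                   d_nm = d[acc]),
    unpaired = which(!used)
  )
}

# vectorised core: features + z assignment + wobble correction for aligned
# peak pairs; returns localisation rows without the distance/ratio filters
localise_pairs <- function(peak_a, peak_b, model, params) {
  feats <- pair_features(peak_a, peak_b, params$pixel_size_nm)
  ev <- evaluate_model(model, feats$theta_deg)
  kept <- ev$in_range
  tibble(
    x_nm = ifelse(kept, feats$mid_x_nm - ev$dx_nm, feats$mid_x_nm),
    y_nm = ifelse(kept, feats$mid_y_nm - ev$dy_nm, feats$mid_y_nm),
    z_nm = ev$z_nm,
    intensity = feats$total_intensity,
    angle_deg = feats$theta_deg,
    interlobe_nm = feats$d_nm,
    ratio = feats$ratio,
    kept = kept,
    reject_reason = ifelse(kept, "none", "angle_range")
  )
}

#' Convert one lobe pair into a 3D localisation
#'
#' Computes the pair features, predicts z from the rotation angle through
#' the calibration, and corrects the midpoint by the expected wobble shift
#' at that angle. Pairs whose angle falls outside the calibration's usable
#' range are marked `kept = FALSE` with reason `"angle_range"` (their z
#' cannot be identified reliably). Distance/ratio filters are applied
#' separately by [apply_filters()].
#'
#' @param peak_a,peak_b One-row peak tibbles from the same frame.
#' @param model A `dh_calibration`.
#' @param params A [unmix_params()].
#' @return A one-row localisation tibble.
#' @export
localise <- function(peak_a, peak_b, model, params) {
  localise_pairs(peak_a, peak_b, model, params)
}

#' Filter localisations against the calibration's distance and ratio curves
#'
#' A localisation with angle in range is rejected with reason `"distance"`
#' when `|d_obs - d(theta)| > tol_d * d(theta)`, else with reason `"ratio"`
#' when `|log(r_obs) - log(r(theta))| > log(1 + tol_r)`; otherwise it is
#' kept. Rows already rejected for `"angle_range"` are left untouched.
#'
#' @param locs Localisation tibble (from [localise()] / [unmix_stack()]).
#' @param model A `dh_calibration`.
#' @param params A [unmix_params()].
#' @return The tibble with `kept` / `reject_reason` updated.
#' @export
apply_filters <- function(locs, model, params) {
  idx <- which(locs$reject_reason != "angle_range")
  if (length(idx) == 0L) return(locs)
  ev <- evaluate_model(model, locs$angle_deg[idx])
  bad_d <- abs(locs$interlobe_nm[idx] - ev$d_nm) > params$tol_d * ev$d_nm
  bad_r <- abs(log(locs$ratio[idx]) - log(ev$ratio)) > log(1 + params$tol_r)
  reason <- ifelse(bad_d, "distance", ifelse(bad_r, "ratio", "none"))
  locs$reject_reason[idx] <- reason
  locs$kept[idx] <- reason == "none"
  locs
}

#' Convert a 2D peak table into 3D localisations
#'
#' Frame by frame: [pair_peaks()] (pairwise distance matrix with greedy
#' conflict resolution), [localise()] (z from the rotation angle, wobble
#' correction) and [apply_filters()] (calibration-relative distance and
#' ratio tolerances). Rejected localisations remain in the output with
#' their `reject_reason`; downstream exports such as [write_visp()] use
#' only kept rows.
#'
#' @param peaks Peak tibble sorted by frame (see [detect_stack()] /
#'   [read_peak_table()]).
#' @param model A `dh_calibration`.
#' @param params A [unmix_params()]; defaults derived from `model`.
#' @return A localisation tibble with columns `frame`, `x_nm`, `y_nm`,
#'   `z_nm`, `intensity`, `angle_deg`, `interlobe_nm`, `ratio`, `kept`,
#'   `reject_reason`, in frame order. Counts of rejections by reason and of
#'   unpaired peaks are attached as attribute `"unmix_log"`.
#' @export
unmix_stack <- function(peaks, model, params = unmix_params(model)) {
  stopifnot(inherits(model, "dh_calibration"))
  frames <- unique(peaks$frame)
  out <- vector("list", length(frames))
  n_unpaired <- 0L
  for (k in seq_along(frames)) {
    fp <- peaks[peaks$frame == frames[k], ]
    pr <- pair_peaks(fp, params)
    n_unpaired <- n_unpaired + length(pr$unpaired)
    if (nrow(pr$pairs) == 0L) next
    loc <- localise_pairs(fp[pr$pairs$i, ], fp[pr$pairs$j, ], model, params)
    loc <- apply_filters(loc, model, params)
    loc$frame <- frames[k]
    out[[k]] <- loc
  }
  locs <- bind_rows(out)
  if (nrow(locs) == 0L) {
    locs <- tibble(frame = integer(), x_nm = numeric(), y_nm = numeric(),
                   z_nm = numeric(), intensity = numeric(), angle_deg = numeric(),
                   interlobe_nm = numeric(), ratio = numeric(), kept = logical(),
                   reject_reason = character())
  } else {
    locs <- locs[c("frame", "x_nm", "y_nm", "z_nm", "intensity", "angle_deg",
                   "interlobe_nm", "ratio", "kept", "reject_reason")]
  }
  attr(locs, "unmix_log") <- c(
    table(factor(locs$reject_reason, levels = c("none", "angle_range", "distance", "ratio"))),
    unpaired = n_unpaired
  )
  locs
}
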