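# File dialects: grayscale TIFF stacks, CSV peak/localisation tables (native
# and an external-fitter column mapping), tab-separated ViSP export, and a
# JSON calibration-model file.

#' Image stack container
#'
#' A minimal in-memory representation of a multi-frame grayscale image stack:
#' a list of numeric matrices (row = y, column = x; pixel centres at integer
#' 0-based coordinates) plus the lateral pixel size. The pixel size is user
#' metadata, not read from TIFF tags: it is typically measured with a grating
#' target rather than trusted from acquisition software.
#'
#' @param frames List of numeric matrices, all of the same dimension.
#' @param pixel_size_nm Lateral pixel size in nm.
#' @return An object of class `dh_stack` with fields `frames`,
#'   `pixel_size_nm`, `n_frames`, `height`, `width`.
#' @export
dh_stack <- function(frames, pixel_size_nm) {
  if (!is.list(frames) || length(frames) == 0L) abort("`frames` must be a non-empty list of matrices.")
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    abort("all frames must share the same height x width.")
  }
  assert_number(pixel_size_nm, "pixel_size_nm", positive = TRUE)
  structure(
    list(frames = frames, pixel_size_nm = pixel_size_nm,
         n_frames = length(frames), height = dims[1, 1], width = dims[2, 1]),
    class = "dh_stack"
  )
}

#' @export
print.dh_stack <- function(x, ...) {
  cat(sprintf("<dh_stack> %d frame(s), %d x %d px, pixel %g nm\n",
              x$n_frames, x$width, x$height, x$pixel_size_nm))
  invisible(x)
}

#' Read a grayscale TIFF stack
#'
#' Reads a single- or multi-page grayscale TIFF in page order. Integer
#' sample formats are returned as raw counts; float TIFFs are returned as
#' stored.
#'
#' @param path Path to the TIFF file.
#' @param pixel_size_nm Lateral pixel size in nm (user-supplied metadata).
#' @return A [dh_stack()].
#' @export
read_image_stack <- function(path, pixel_size_nm) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (length(pages) == 0L) abort("TIFF contains zero pages.")
  if (any(vapply(pages, function(p) length(dim(p)) != 2L, logical(1)))) {
    abort("unsupported format: RGB/multi-channel TIFF; a grayscale stack is required.")
  }
  dh_stack(lapply(pages, function(p) {
    storage.mode(p) <- "double"
    p
  }), pixel_size_nm)
}

#' Write a stack as a 16-bit grayscale TIFF
#'
#' Counts are rounded and clamped to the 16-bit range \[0, 65535\], the
#' storage format of typical camera data; integer-valued stacks round-trip
#' exactly through [read_image_stack()].
#'
#' @param stack A [dh_stack()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_image_stack <- function(stack, path) {
  stopifnot(inherits(stack, "dh_stack"))
  pages <- lapply(stack$frames, function(f) pmin(pmax(round(f), 0), 65535) / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16)
  invisible(path)
}

# column mapping of the external fitter's results table onto native names;
# best effort, matched case-insensitively
.gdsc_columns <- c(
  frame = "frame", x = "x_px", y = "y_px", signal = "intensity",
  sd = "sigma_px", background = "background"
)

#' Read a 2D peak table
#'
#' The native dialect is a comma-separated file with header columns `frame`
#' (0-based), `x_px`, `y_px` (sub-pixel pixel coordinates), `intensity`, and
#' optionally `sigma_px` and `background`. The `gdsc` dialect maps an
#' external fitter's column names (`Frame`, `X`, `Y`, `Signal`, `SD`,
#' `Background`; matched case-insensitively) onto the native fields; its
#' coordinates are likewise interpreted as pixels. Rows are returned sorted
#' by frame.
#'
#' @param path Path to a delimited text file with a header.
#' @param dialect `"native"` or `"gdsc"`.
#' @return A tibble (one row per fitted lobe) sorted by frame.
#' @export
read_peak_table <- function(path, dialect = c("native", "gdsc")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  raw <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (dialect == "gdsc") {
    lower <- tolower(names(raw))
    keep <- lower %in% names(.gdsc_columns)
    raw <- raw[keep]
    names(raw) <- unname(.gdsc_columns[lower[keep]])
  }
  required <- c("frame", "x_px", "y_px", "intensity")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    abort(sprintf("peak table is missing mandatory column(s): %s",
                  paste(missing, collapse = ", ")))
  }
  for (col in intersect(c(required, "sigma_px", "background"), names(raw))) {
    v <- raw[[col]]
    if (!is.numeric(v)) {
      v2 <- suppressWarnings(as.numeric(v))
      if (anyNA(v2) && !anyNA(v)) abort(sprintf("non-numeric value in column `%s`.", col))
      raw[[col]] <- v2
    }
  }
  if (!"sigma_px" %in% names(raw)) raw$sigma_px <- NA_real_
  if (!"background" %in% names(raw)) raw$background <- NA_real_
  out <- as_tibble(raw[c("frame", "x_px", "y_px", "intensity", "sigma_px", "background")])
  out$frame <- as.integer(out$frame)
  arrange(out, .data$frame)
}

#' Write a peak table in the native CSV dialect
#'
#' @param peaks Peak tibble (see [read_peak_table()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peak_table <- function(peaks, path) {
  write.csv(peaks, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a 3D localisation table (native CSV)
#'
#' Columns: `frame`, `x_nm`, `y_nm`, `z_nm`, `intensity`, `angle_deg`,
#' `interlobe_nm`, `ratio`, `kept`, `reject_reason`.
#'
#' @param path File path.
#' @return A tibble.
#' @export
read_localisation_table <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  out <- as_tibble(read.csv(path, stringsAsFactors = FALSE))
  if ("kept" %in% names(out)) out$kept <- as.logical(out$kept)
  out
}

#' @rdname read_localisation_table
#' @param locs Localisation tibble.
#' @export
write_localisation_table <- function(locs, path) {
  write.csv(locs, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export kept localisations for ViSP
#'
#' Writes the tab-separated, headerless format consumed by the ViSP 3D
#' viewer: `x_nm y_nm z_nm intensity frame`, one line per kept localisation.
#'
#' @param locs Localisation tibble; only rows with `kept == TRUE` are
#'   exported (all rows if there is no `kept` column).
#' @param path Output path.
#' @return `path`, invisibly. Writes an empty file with a warning when no
#'   localisation survives filtering.
#' @export
write_visp <- function(locs, path) {
  if ("kept" %in% names(locs)) locs <- locs[locs$kept, ]
  if (nrow(locs) == 0L) {
    warn("no kept localisations; writing an empty ViSP file")
    writeLines(character(0), path)
    return(invisible(path))
  }
  lines <- sprintf("%.1f\t%.1f\t%.1f\t%.1f\t%d",
                   locs$x_nm, locs$y_nm, locs$z_nm, locs$intensity,
                   as.integer(locs$frame))
  writeLines(lines, path)
  invisible(path)
}

.model_format_version <- "1.0"

#' Save / load a calibration model
#'
#' The model is stored as human-readable JSON: polynomial degree, Chebyshev
#' coefficients of the five calibration curves, the usable angle range,
#' pixel size and axial step. The round trip is lossless to full double
#' precision.
#'
#' @param model A `dh_calibration` (see [build_calibration()]).
#' @param path File path.
#' @return `save_calibration`: `path`, invisibly. `load_calibration`: the
#'   restored `dh_calibration`.
#' @export
save_calibration <- function(model, path) {
  stopifnot(inherits(model, "dh_calibration"))
  payload <- list(
    format = "helixloc-calibration",
    version = .model_format_version,
    degree = model$degree,
    theta_range = model$theta_range,
    pixel_size_nm = model$pixel_size_nm,
    z_step_nm = model$z_step_nm,
    z_offset_nm = model$z_offset_nm,
    curves = lapply(model$curves, function(f) {
      list(coef = f$coef, degree = f$degree, xlim = f$xlim)
    }),
    residual_rms = as.list(model$residual_rms),
    n_frames_used = model$n_frames_used
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname save_calibration
#' @export
load_calibration <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  payload <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                      error = function(e) abort("malformed calibration file."))
  if (!identical(payload$format, "helixloc-calibration")) {
    abort("not a helixloc calibration file.")
  }
  if (!identical(as.character(payload$version), .model_format_version)) {
    abort(sprintf("calibration file version mismatch: %s (expected %s).",
                  payload$version, .model_format_version))
  }
  required <- c("degree", "theta_range", "pixel_size_nm", "z_step_nm", "curves")
  missing <- setdiff(required, names(payload))
  if (length(missing) > 0) {
    abort(sprintf("calibration file missing field(s): %s", paste(missing, collapse = ", ")))
  }
  curves <- lapply(payload$curves, function(f) {
    list(coef = as.numeric(f$coef), degree = as.integer(f$degree), xlim = as.numeric(f$xlim))
  })
  structure(
    list(
      degree = as.integer(payload$degree),
      theta_range = as.numeric(payload$theta_range),
      pixel_size_nm = as.numeric(payload$pixel_size_nm),
      z_step_nm = as.numeric(payload$z_step_nm),
      z_offset_nm = as.numeric(payload$z_offset_nm %||% 0),
      curves = curves,
      residual_rms = unlist(payload$residual_rms),
      n_frames_used = as.integer(payload$n_frames_used %||% NA_integer_),
      features = NULL
    ),
    class = "dh_calibration"
  )
}
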