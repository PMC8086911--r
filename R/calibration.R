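#' Camera calibration model
#'
#' A calibration object holds everything needed to turn raw linear sensor
#' counts from a fisheye camera into absolute photon radiance: per-channel
#' scale constants, sensor black/white levels, relative gain tables for ISO
#' and aperture, a vignetting table sampled at 10-degree steps of off-axis
#' angle for each calibrated aperture, and the fisheye projection geometry.
#'
#' The default object describes an idealised camera used by the synthetic
#' renderer: a 500 x 500 sensor with a 250-px-radius equisolid image
#' circle, 14-bit-like levels, unit gain at ISO 100 / f/3.5, and a mild
#' quadratic vignetting fall-off.
#'
#' @param channels Named list of per-channel scale constants K_ch
#'   (photon radiance per count-per-second at reference gains), with names
#'   red, green, blue.
#' @param black_level,white_level Sensor levels in counts;
#'   `black_level < white_level`.
#' @param iso_gain Named list mapping ISO setting to relative gain
#'   (1 at the reference ISO).
#' @param aperture_gain Named list mapping f-number to relative
#'   transmission (1 at the reference aperture).
#' @param vignetting Named list mapping f-number to a 10-element numeric
#'   vector of relative transmission V(theta) at theta = 0, 10, ..., 90
#'   degrees; V(0) = 1 and 0 < V <= 1.
#' @param projection List with elements `model` (only "equisolid"),
#'   `center_xy` (image-circle centre, pixel coordinates x = column,
#'   y = row) and `radius_px` (circle radius in pixels).
#' @return An object of class `camera_calibration`.
#' @export
camera_calibration <- function(channels = list(red = 1.1e9, green = 0.9e9, blue = 1.3e9),
                               black_level = 400,
                               white_level = 16200,
                               iso_gain = list(`100` = 1, `200` = 2, `400` = 4, `800` = 8),
                               aperture_gain = list(`3.5` = 1,
                                                    `8` = (3.5 / 8)^2,
                                                    `22` = (3.5 / 22)^2),
                               vignetting = default_vignetting(),
                               projection = list(model = "equisolid",
                                                 center_xy = c(250.5, 250.5),
                                                 radius_px = 250)) {
  cal <- structure(
    list(
      channels = channels,
      black_level = black_level,
      white_level = white_level,
      iso_gain = iso_gain,
      aperture_gain = aperture_gain,
      vignetting = vignetting,
      projection = projection
    ),
    class = "camera_calibration"
  )
  validate_calibration(cal)
  cal
}

default_vignetting <- function() {
  theta <- seq(0, 90, by = 10)
  list(
    `3.5` = 1 - 0.30 * (theta / 90)^2,
    `8` = 1 - 0.20 * (theta / 90)^2,
    `22` = 1 - 0.10 * (theta / 90)^2
  )
}

#' Validate a camera calibration object
#'
#' Checks the structural invariants of the calibration model and fails
#' with an informative message naming the offending field.
#'
#' @param cal Object to validate.
#' @return `cal`, invisibly, if valid.
#' @export
validate_calibration <- function(cal) {
  if (!inherits(cal, "camera_calibration")) {
    abort("`cal` must be a camera_calibration object.")
  }
  required <- c("channels", "black_level", "white_level", "iso_gain",
                "aperture_gain", "vignetting", "projection")
  missing <- setdiff(required, names(cal))
  if (length(missing)) {
    abort(paste0("Calibration is missing field(s): ",
                 paste(missing, collapse = ", "), "."))
  }
  if (!all(c("red", "green", "blue") %in% names(cal$channels))) {
    abort("Calibration `channels` must name red, green and blue.")
  }
  if (any(unlist(cal$channels) <= 0)) {
    abort("Channel constants K_ch must be positive.")
  }
  if (cal$black_level >= cal$white_level) {
    abort("`black_level` must be below `white_level`.")
  }
  for (ap in names(cal$vignetting)) {
    v <- cal$vignetting[[ap]]
    if (length(v) != 10L) {
      abort(paste0("Vignetting table for f/", ap,
                   " must have 10 entries (0..90 degrees by 10)."))
    }
    if (abs(v[1] - 1) > 1e-9) {
      abort(paste0("Vignetting table for f/", ap, " must have V(0) = 1."))
    }
    if (any(v <= 0 | v > 1 + 1e-9)) {
      abort(paste0("Vignetting for f/", ap, " must satisfy 0 < V <= 1."))
    }
  }
  pr <- cal$projection
  if (!identical(pr$model, "equisolid")) {
    abort("Only the 'equisolid' projection model is supported.")
  }
  if (length(pr$center_xy) != 2L || pr$radius_px <= 0) {
    abort("Projection needs `center_xy` (x, y) and positive `radius_px`.")
  }
  invisible(cal)
}

# Lookup with exact-match keys and nearest-key fallback (with warning).
lookup_gain <- function(table, key, what) {
  keys <- as.numeric(names(table))
  exact <- which(abs(keys - key) < 1e-9)
  if (length(exact)) return(table[[exact[1]]])
  if (!length(keys)) abort(paste0("Calibration has no ", what, " entries."))
  nearest <- which.min(abs(keys - key))
  warn(paste0("No ", what, " calibration for ", key, "; using nearest (",
              names(table)[nearest], ")."))
  table[[nearest]]
}

iso_gain <- function(cal, iso) {
  if (iso <= 0) abort("`iso` must be positive.")
  lookup_gain(cal$iso_gain, iso, "ISO")
}

aperture_gain <- function(cal, f_number) {
  if (f_number <= 0) abort("`f_number` must be positive.")
  lookup_gain(cal$aperture_gain, f_number, "aperture")
}

# V(theta) by linear interpolation between the 10-degree table entries;
# nearest calibrated aperture (with warning) if f_number is uncalibrated.
vignetting_at <- function(cal, theta, f_number) {
  v_table <- lookup_gain(cal$vignetting, f_number, "vignetting aperture")
  grid <- seq(0, 90, by = 10)
  out <- approx(grid, v_table, xout = as.vector(theta), rule = 2)$y
  if (!is.null(dim(theta))) dim(out) <- dim(theta)
  out
}

#' Read and write calibration files
#'
#' Calibration files are JSON documents with keys `channels`,
#' `black_level`, `white_level`, `iso_gain`, `aperture_gain`, `vignetting`
#' (one 10-element vector per aperture) and `projection`. Files are
#' strictly validated on read.
#'
#' @param path Path to a calibration JSON file.
#' @param cal A [camera_calibration()] object.
#' @return `read_calibration()` returns a validated `camera_calibration`;
#'   `write_calibration()` returns `path` invisibly.
#' @export
read_calibration <- function(path) {
  if (!file.exists(path)) abort(paste0("Calibration file not found: ", path))
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  cal <- structure(
    list(
      channels = as.list(raw$channels),
      black_level = raw$black_level,
      white_level = raw$white_level,
      iso_gain = as.list(raw$iso_gain),
      aperture_gain = as.list(raw$aperture_gain),
      vignetting = lapply(raw$vignetting, as.numeric),
      projection = list(
        model = raw$projection$model,
        center_xy = as.numeric(raw$projection$center_xy),
        radius_px = raw$projection$radius_px
      )
    ),
    class = "camera_calibration"
  )
  validate_calibration(cal)
  cal
}

#' @rdname read_calibration
#' @export
write_calibration <- function(cal, path) {
  validate_calibration(cal)
  jsonlite::write_json(unclass(cal), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @export
print.camera_calibration <- function(x, ...) {
  cat("<camera_calibration>\n")
  cat("  channels K:", paste(names(x$channels), unlist(x$channels),
                             sep = "=", collapse = ", "), "\n")
  cat("  levels: black", x$black_level, "| white", x$white_level, "\n")
  cat("  apertures:", paste(names(x$vignetting), collapse = ", "), "\n")
  cat("  projection:", x$projection$model, "| R_px =",
      x$projection$radius_px, "\n")
  invisible(x)
}
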