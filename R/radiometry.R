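#' Photon radiance in log10 units ("lit")
#'
#' Environmental light is quantified as photon flux radiance, in
#' photons s^-1 m^-2 sr^-1 nm^-1. Because naturally occurring values span
#' around nine orders of magnitude, radiances are reported as log10 values;
#' one unit of log10 photon radiance is abbreviated "lit". `to_lit()`
#' converts linear photon radiance to lit, `from_lit()` inverts it.
#'
#' @param radiance Numeric vector or array of linear photon radiances
#'   (photons s^-1 m^-2 sr^-1 nm^-1). Must be finite and strictly positive;
#'   zero or negative values indicate that the dark-noise floor clamp was
#'   skipped upstream (see [counts_to_radiance()]).
#' @param lit Numeric vector of log10 photon radiances.
#' @return `to_lit()` returns log10(radiance); `from_lit()` returns
#'   10^lit. Shapes are preserved.
#' @examples
#' to_lit(1e11) # 11 lit
#' from_lit(16.5) # 10^16.5
#' @export
to_lit <- function(radiance) {
  if (any(!is.finite(radiance))) {
    abort("`radiance` contains non-finite values: corrupt radiance data.")
  }
  if (any(radiance <= 0)) {
    abort(paste0(
      "`radiance` contains values <= 0; clamp to the dark-noise floor ",
      "before taking logs (see counts_to_radiance())."
    ))
  }
  log10(radiance)
}

#' @rdname to_lit
#' @export
from_lit <- function(lit) {
  if (any(!is.finite(lit))) {
    abort("`lit` contains non-finite values.")
  }
  10^lit
}

#' Linear factor and percent change corresponding to a span in lit
#'
#' A difference of `span` lit corresponds to a linear radiance factor of
#' 10^span. A change of 0.01 lit is a linear change of only 2.3%, which is
#' why two decimal places of lit suffice for typical measurements.
#'
#' @param span Numeric vector of widths/differences in lit units.
#' @return `lit_span_to_factor()` returns the linear factor 10^span;
#'   `lit_span_to_percent()` returns the percent change (10^span - 1) * 100.
#' @examples
#' lit_span_to_percent(0.01) # ~2.3 percent
#' lit_span_to_factor(2) # 100
#' @export
lit_span_to_factor <- function(span) {
  if (any(!is.finite(span))) abort("`span` must be finite.")
  10^span
}

#' @rdname lit_span_to_factor
#' @export
lit_span_to_percent <- function(span) {
  (lit_span_to_factor(span) - 1) * 100
}

#' Exposure-value steps to linear exposure factor
#'
#' One EV step is a factor-2 change in exposure; a 3 EV step is a factor 8,
#' and a three-exposure bracket with 3 EV spacing spans 6 EV, a factor 64.
#'
#' @param delta_ev Numeric vector of EV differences.
#' @return 2^delta_ev.
#' @examples
#' ev_to_factor(3) # 8
#' ev_to_factor(6) # 64
#' @export
ev_to_factor <- function(delta_ev) {
  if (any(!is.finite(delta_ev))) abort("`delta_ev` must be finite.")
  2^delta_ev
}

#' Percent difference in photon energy between two wavelengths
#'
#' Photoreceptors count photons rather than measure energy. Photon energy
#' E = hc/lambda, so across the visible band the energy per photon differs
#' substantially: between 400 and 700 nm it differs by 75%.
#'
#' @param lambda1,lambda2 Wavelengths in nm; both must be positive.
#' @return Percent difference (E(lambda1)/E(lambda2) - 1) * 100.
#' @examples
#' photon_energy_percent_diff(400, 700) # 75
#' @export
photon_energy_percent_diff <- function(lambda1, lambda2) {
  if (any(lambda1 <= 0) || any(lambda2 <= 0)) {
    abort("Wavelengths must be positive.")
  }
  e1 <- PLANCK_H * LIGHT_C / (lambda1 * 1e-9)
  e2 <- PLANCK_H * LIGHT_C / (lambda2 * 1e-9)
  (e1 / e2 - 1) * 100
}

#' Convert energy radiance to photon radiance
#'
#' Converts spectral energy radiance (W m^-2 sr^-1 nm^-1) at wavelength
#' lambda to photon radiance by dividing by the photon energy hc/lambda.
#'
#' @param radiance_e Energy radiance, W m^-2 sr^-1 nm^-1 (>= 0).
#' @param lambda Wavelength in nm (> 0).
#' @return Photon radiance, photons s^-1 m^-2 sr^-1 nm^-1.
#' @examples
#' to_lit(energy_to_photon_radiance(1, 500)) # ~18.4 lit
#' @export
energy_to_photon_radiance <- function(radiance_e, lambda) {
  if (any(lambda <= 0)) abort("`lambda` must be positive.")
  if (any(radiance_e < 0)) abort("`radiance_e` must be non-negative.")
  radiance_e * (lambda * 1e-9) / (PLANCK_H * LIGHT_C)
}

#' Spectral bands used for environmental light analysis
#'
#' The analysis uses three contiguous 100-nm slots matched to the broad
#' spectral channels of RGB sensors and of human photoreceptors, plus a
#' white band integrating all three.
#'
#' @return A tibble with columns `band`, `lambda_min`, `lambda_max` (nm).
#' @export
spectral_bands <- function() {
  tibble(
    band = c("blue", "green", "red", "white"),
    lambda_min = c(400, 500, 600, 400),
    lambda_max = c(500, 600, 700, 700)
  )
}

#' Convert sensor counts to photon radiance
#'
#' Applies the radiometric camera model
#' `L = (counts - black_level) * K_ch / (t * iso_gain(S) * aperture_gain(N))`
#' per channel, where K_ch is the channel's calibration constant at the
#' reference exposure settings. After black-level subtraction, values <= 0
#' are clamped to a dark-noise floor of 1e-3 times the smallest positive
#' radiance in the image, so downstream log statistics stay finite. Pixels
#' at or above 99% of the white level are flagged as saturated.
#'
#' @param counts Numeric matrix (one channel) or H x W x 3 array (RGB) of
#'   raw linear sensor counts in `[0, white_level]`.
#' @param exposure_time Exposure time in seconds (> 0).
#' @param iso ISO setting (> 0); looked up in the calibration's gain table.
#' @param f_number Aperture f-number (> 0); looked up likewise.
#' @param cal A [camera_calibration()] object.
#' @param channel For matrix input, which channel's constant to use
#'   ("red", "green" or "blue").
#' @return A list with elements `radiance` (same shape as `counts`) and
#'   `saturated` (logical matrix; for RGB input, TRUE where any channel
#'   saturates).
#' @export
counts_to_radiance <- function(counts, exposure_time, iso, f_number, cal,
                               channel = NULL) {
  validate_calibration(cal)
  if (exposure_time <= 0) abort("`exposure_time` must be positive.")
  g <- exposure_time * iso_gain(cal, iso) * aperture_gain(cal, f_number)
  dims <- dim(counts)
  rgb_input <- length(dims) == 3L && dims[3] == 3L
  chans <- c("red", "green", "blue")
  if (!rgb_input) {
    if (is.null(channel)) {
      abort("`channel` must name a calibrated channel for matrix input.")
    }
    if (!channel %in% names(cal$channels)) {
      abort(paste0("No calibration constant for channel '", channel, "'."))
    }
  }
  sat_threshold <- 0.99 * cal$white_level
  if (rgb_input) {
    radiance <- array(NA_real_, dims)
    for (k in seq_len(3L)) {
      radiance[, , k] <- (counts[, , k] - cal$black_level) *
        cal$channels[[chans[k]]] / g
    }
    saturated <- (counts[, , 1] >= sat_threshold) |
      (counts[, , 2] >= sat_threshold) |
      (counts[, , 3] >= sat_threshold)
  } else {
    radiance <- (counts - cal$black_level) * cal$channels[[channel]] / g
    saturated <- counts >= sat_threshold
  }
  radiance <- clamp_radiance_floor(radiance)
  list(radiance = radiance, saturated = saturated)
}

# Dark-noise floor: values <= 0 after black subtraction become
# 1e-3 * smallest positive value, keeping log spans finite.
clamp_radiance_floor <- function(radiance) {
  pos <- radiance[radiance > 0]
  floor_val <- if (length(pos)) 1e-3 * min(pos) else 1e-3
  radiance[radiance <= 0] <- floor_val
  radiance
}

#' Correct off-axis vignetting
#'
#' Divides each pixel by the lens transmission V(theta) interpolated
#' linearly in the off-axis angle theta from the calibration's 10-degree
#' vignetting table for the given aperture. If the aperture was not
#' calibrated, the nearest calibrated aperture is used with a warning.
#'
#' @param radiance Numeric matrix or H x W x 3 array of linear radiances.
#' @param theta Matrix of off-axis angles in degrees, same H x W as
#'   `radiance`; all values must lie in `[0, 90]` (NA allowed for pixels
#'   outside the image circle).
#' @param cal A [camera_calibration()] object.
#' @param f_number Aperture used for the exposure.
#' @return Corrected radiance with the shape of the input.
#' @export
vignetting_correct <- function(radiance, theta, cal, f_number) {
  if (any(theta < 0 | theta > 90, na.rm = TRUE)) {
    abort("`theta` outside [0, 90] degrees: geometry bug.")
  }
  v <- vignetting_at(cal, theta, f_number)
  if (length(dim(radiance)) == 3L) {
    for (k in seq_len(dim(radiance)[3])) {
      radiance[, , k] <- radiance[, , k] / v
    }
    radiance
  } else {
    radiance / v
  }
}

#' White-band radiance from the three colour bands
#'
#' The white band (400-700 nm) is the per-nm average of the three 100-nm
#' colour slots: (R + G + B) / 3. Averaging (rather than summing) keeps the
#' unit per nm, so white radiances are directly comparable to band
#' radiances.
#'
#' @param red,green,blue Linear photon radiances (per nm within each band);
#'   vectors or arrays of identical shape.
#' @return Linear white photon radiance, same shape.
#' @examples
#' white_from_rgb(1e16, 1e16, 1e16) # 1e16
#' @export
white_from_rgb <- function(red, green, blue) {
  if (any(red < 0) || any(green < 0) || any(blue < 0)) {
    abort("Band radiances must be non-negative.")
  }
  (red + green + blue) / 3
}
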