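#' Fisheye exposure container
#'
#' One exposure taken through a circular 180-degree fisheye lens held
#' horizontally, so the image equator is the horizontal plane, the top of
#' the circle is the zenith (+90 degrees elevation) and the bottom the
#' nadir (-90 degrees). Pixel coordinates are x = column, y = row (y grows
#' downwards), with pixel centres at integer coordinates.
#'
#' @param pixels H x W x 3 numeric array (red, green, blue planes) of
#'   linear sensor counts or linear radiances.
#' @param exposure_time Exposure time, seconds.
#' @param iso ISO setting.
#' @param f_number Aperture f-number.
#' @param ev_offset Bracketing offset in EV units relative to the middle
#'   exposure.
#' @param center Image-circle centre `c(x, y)` in pixels.
#' @param radius_px Image-circle radius in pixels (> 0); the circle must
#'   fit inside the raster.
#' @param unit Either "counts" (raw sensor data) or "radiance"
#'   (calibrated photon radiance).
#' @param saturated Optional logical H x W matrix flagging saturated
#'   pixels.
#' @param model Projection model; only "equisolid" is implemented.
#' @return An object of class `fisheye_exposure`.
#' @export
fisheye_exposure <- function(pixels, exposure_time, iso = 100, f_number = 3.5,
                             ev_offset = 0, center = NULL, radius_px = NULL,
                             unit = c("counts", "radiance"),
                             saturated = NULL, model = "equisolid") {
  unit <- match.arg(unit)
  dims <- dim(pixels)
  if (length(dims) != 3L || dims[3] != 3L) {
    abort("`pixels` must be an H x W x 3 array.")
  }
  h <- dims[1]; w <- dims[2]
  if (is.null(center)) center <- c((w + 1) / 2, (h + 1) / 2)
  if (is.null(radius_px)) radius_px <- min(w, h) / 2
  if (radius_px <= 0) abort("`radius_px` must be positive.")
  if (!identical(model, "equisolid")) {
    abort("Only the 'equisolid' projection model is implemented.")
  }
  if (center[1] + radius_px > w + 0.5 || center[1] - radius_px < 0.5 ||
      center[2] + radius_px > h + 0.5 || center[2] - radius_px < 0.5) {
    abort("Image circle does not fit inside the raster.")
  }
  structure(
    list(
      pixels = pixels,
      meta = list(exposure_time = exposure_time, iso = iso,
                  f_number = f_number, ev_offset = ev_offset),
      center = center, radius_px = radius_px, unit = unit,
      saturated = saturated, model = model
    ),
    class = "fisheye_exposure"
  )
}

#' @export
print.fisheye_exposure <- function(x, ...) {
  d <- dim(x$pixels)
  cat("<fisheye_exposure> ", d[1], "x", d[2], " (", x$unit, "), R_px = ",
      x$radius_px, ", t = ", x$meta$exposure_time, " s, EV ",
      sprintf("%+g", x$meta$ev_offset), "\n", sep = "")
  invisible(x)
}

#' Equisolid radius/angle conversions
#'
#' An equisolid fisheye maps off-axis angle theta to radial image distance
#' r = 2 f sin(theta / 2). Normalised to the 180-degree image circle
#' (theta = 90 degrees at the rim), r_norm = sin(theta / 2) / sin(45deg),
#' so theta = 2 asin(r_norm sin(45deg)).
#'
#' @param r_norm Radial distance normalised by the circle radius, in
#'   `[0, 1]`; values > 1 (outside the image circle) return NA.
#' @param theta Off-axis angle in degrees, in `[0, 90]`.
#' @return `radius_to_theta()` returns theta in degrees;
#'   `theta_to_radius()` returns r_norm.
#' @examples
#' radius_to_theta(c(0, 0.5, 1)) # 0, 41.41, 90
#' @export
radius_to_theta <- function(r_norm) {
  if (any(r_norm < 0, na.rm = TRUE)) abort("`r_norm` must be >= 0.")
  out <- 2 * asin(pmin(r_norm, 1) * sin(pi / 4)) * 180 / pi
  out[r_norm > 1] <- NA_real_
  out
}

#' @rdname radius_to_theta
#' @export
theta_to_radius <- function(theta) {
  if (any(theta < 0 | theta > 90, na.rm = TRUE)) {
    abort("`theta` must lie in [0, 90] degrees.")
  }
  sin(theta * pi / 360) / sin(pi / 4)
}

#' Map image points to viewing directions
#'
#' For a horizontal camera, converts fisheye pixel positions to viewing
#' directions. With psi the position angle measured from image-up and
#' theta the off-axis angle, the direction has elevation
#' `asin(sin(theta) cos(psi))` and azimuth `atan2(sin(theta) sin(psi),
#' cos(theta))` relative to the optical axis.
#'
#' @param x,y Pixel coordinates (x = column, y = row, y grows downwards).
#' @param center Image-circle centre `c(x, y)`.
#' @param radius_px Image-circle radius in pixels.
#' @return A tibble with columns `x`, `y`, `theta`, `elevation`,
#'   `azimuth` (degrees) and `valid` (inside the image circle). Outside
#'   the circle the angles are NA.
#' @export
image_point_to_direction <- function(x, y, center, radius_px) {
  x <- as.vector(x)
  y <- as.vector(y)
  dx <- (x - center[1]) / radius_px
  dy <- (y - center[2]) / radius_px
  r_norm <- sqrt(dx^2 + dy^2)
  valid <- r_norm <= 1 + 1e-12
  theta <- radius_to_theta(pmin(r_norm, 1))
  psi <- atan2(dx, -dy) # 0 at image-up, +90 deg at image-right
  th <- theta * pi / 180
  elevation <- asin(pmin(1, pmax(-1, sin(th) * cos(psi)))) * 180 / pi
  azimuth <- atan2(sin(th) * sin(psi), cos(th)) * 180 / pi
  elevation[!valid] <- NA_real_
  azimuth[!valid] <- NA_real_
  theta[!valid] <- NA_real_
  tibble(x = x, y = y, theta = theta, elevation = elevation,
         azimuth = azimuth, valid = valid)
}

# Inverse mapping: direction (elevation, azimuth in degrees) to real-valued
# fisheye pixel coordinates. Vectorised; used by the remapper.
direction_to_image_point <- function(elevation, azimuth, center, radius_px) {
  el <- elevation * pi / 180
  az <- azimuth * pi / 180
  d_axis <- cos(el) * cos(az)
  d_up <- sin(el)
  d_right <- cos(el) * sin(az)
  sin_theta <- sqrt(d_up^2 + d_right^2)
  theta <- acos(pmin(1, pmax(-1, d_axis)))
  r_norm <- sin(theta / 2) / sin(pi / 4)
  # unit vector towards the point in the image plane; arbitrary at theta=0
  safe <- sin_theta > 1e-12
  cos_psi <- ifelse(safe, d_up / pmax(sin_theta, 1e-300), 1)
  sin_psi <- ifelse(safe, d_right / pmax(sin_theta, 1e-300), 0)
  list(
    x = center[1] + radius_px * r_norm * sin_psi,
    y = center[2] - radius_px * r_norm * cos_psi,
    theta = theta * 180 / pi
  )
}

# Off-axis angle theta (degrees) for every pixel of a fisheye raster.
fisheye_theta_map <- function(exposure) {
  d <- dim(exposure$pixels)
  x <- matrix(rep(seq_len(d[2]), each = d[1]), d[1], d[2])
  y <- matrix(rep(seq_len(d[1]), times = d[2]), d[1], d[2])
  dx <- (x - exposure$center[1]) / exposure$radius_px
  dy <- (y - exposure$center[2]) / exposure$radius_px
  r_norm <- sqrt(dx^2 + dy^2)
  theta <- radius_to_theta(pmin(r_norm, 1))
  theta[r_norm > 1] <- NA_real_
  theta
}

#' Equirectangular radiance image container
#'
#' The canonical working representation: a square M x M x 3 array whose
#' rows are constant elevation (row 1 is +90 degrees, the last row -90)
#' and whose columns are constant azimuth (column 1 is -90 degrees
#' relative to the optical axis, the last +90). Cell (i, j) covers the
#' half-open angular interval ending at its edges, with angles evaluated
#' at cell centres.
#'
#' @param pixels M x M x 3 numeric array of linear photon radiances
#'   (red, green, blue planes).
#' @param mask Logical M x M matrix; TRUE where the cell holds valid data.
#' @param saturated Logical M x M matrix; TRUE where the radiance is a
#'   lower bound because the sensor saturated in every usable exposure.
#' @return An object of class `equirect_image`.
#' @export
equirect_image <- function(pixels, mask = NULL, saturated = NULL) {
  dims <- dim(pixels)
  if (length(dims) != 3L || dims[1] != dims[2] || dims[3] != 3L) {
    abort("`pixels` must be a square M x M x 3 array.")
  }
  m <- dims[1]
  if (is.null(mask)) mask <- matrix(TRUE, m, m)
  if (is.null(saturated)) saturated <- matrix(FALSE, m, m)
  structure(list(pixels = pixels, mask = mask, saturated = saturated),
            class = "equirect_image")
}

#' @export
print.equirect_image <- function(x, ...) {
  m <- dim(x$pixels)[1]
  cat("<equirect_image> ", m, "x", m, " x 3, ",
      sum(x$mask), " valid px, ", sum(x$saturated), " saturated px\n",
      sep = "")
  invisible(x)
}

#' Elevation and azimuth of equirectangular cell centres
#'
#' @param image An [equirect_image()] (or its side length).
#' @return Numeric vector of cell-centre elevations (rows, +90 down to
#'   -90) or azimuths (columns, -90 to +90), in degrees.
#' @export
equirect_elevations <- function(image) {
  m <- if (inherits(image, "equirect_image")) dim(image$pixels)[1] else image
  90 - 180 * (seq_len(m) - 0.5) / m
}

#' @rdname equirect_elevations
#' @export
equirect_azimuths <- function(image) {
  m <- if (inherits(image, "equirect_image")) dim(image$pixels)[1] else image
  -90 + 180 * (seq_len(m) - 0.5) / m
}

#' Remap a fisheye exposure to the equirectangular grid
#'
#' Performs the angular remapping from the equisolid fisheye projection to
#' an equirectangular elevation x azimuth raster by nearest-neighbour
#' interpolation: each output cell centre is mapped back to its
#' real-valued preimage in the fisheye image and takes the value of the
#' nearest source pixel. No new pixel values are invented. The default
#' output size is the image-circle diameter, preserving equatorial
#' sampling density.
#'
#' @param exposure A [fisheye_exposure()].
#' @param size Output side length M (>= 2); default `2 * radius_px`.
#' @return An [equirect_image()] if the exposure holds radiances,
#'   otherwise a list with the same structure but counts; the exposure's
#'   saturation mask, if any, is remapped alongside.
#' @export
remap_to_equirect <- function(exposure, size = NULL) {
  if (!inherits(exposure, "fisheye_exposure")) {
    abort("`exposure` must be a fisheye_exposure.")
  }
  if (exposure$radius_px <= 0) abort("Degenerate geometry: radius_px <= 0.")
  m <- if (is.null(size)) max(2L, round(2 * exposure$radius_px)) else as.integer(size)
  if (m < 2L) abort("`size` must be at least 2.")
  el <- equirect_elevations(m)
  az <- equirect_azimuths(m)
  # grids: rows = elevation, cols = azimuth
  el_g <- matrix(rep(el, times = m), m, m)
  az_g <- matrix(rep(az, each = m), m, m)
  p <- direction_to_image_point(el_g, az_g, exposure$center,
                                exposure$radius_px)
  xi <- round(p$x)
  yi <- round(p$y)
  d <- dim(exposure$pixels)
  inside <- xi >= 1 & xi <= d[2] & yi >= 1 & yi <= d[1]
  xi[!inside] <- 1L
  yi[!inside] <- 1L
  idx <- cbind(as.vector(yi), as.vector(xi))
  pixels <- array(NA_real_, c(m, m, 3L))
  for (k in seq_len(3L)) {
    plane <- exposure$pixels[, , k]
    pk <- plane[idx]
    pk[!inside] <- NA_real_
    pixels[, , k] <- matrix(pk, m, m)
  }
  mask <- inside
  sat <- if (!is.null(exposure$saturated)) {
    matrix(exposure$saturated[idx] & as.vector(inside), m, m)
  } else {
    matrix(FALSE, m, m)
  }
  out <- equirect_image(pixels, mask = mask, saturated = sat)
  attr(out, "meta") <- exposure$meta
  out
}
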