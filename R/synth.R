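#' Synthetic scene specification
#'
#' Describes a ground-truth light environment that the generator can
#' render and the analysis pipeline should recover: a piecewise-linear
#' elevation profile of median radiance (in lit) per colour band,
#' log-normal azimuthal texture whose width sets the contrast-span, and
#' optional saturating point sources. Rendering is fully reproducible
#' under the stored seed.
#'
#' @param profile A data frame with columns `elevation` (degrees,
#'   covering `[-90, 90]` knots) and `red`, `green`, `blue` (lit at each
#'   knot); values between knots are interpolated linearly, and constant
#'   extrapolation is used beyond the outermost knots.
#' @param sigma Standard deviation, in lit units, of the multiplicative
#'   log-normal azimuthal texture (>= 0). The texture is shared across
#'   bands (achromatic), so band and white contrast-spans coincide.
#' @param sources Optional list of point sources, each a list with
#'   `elevation`, `azimuth`, `radius` (angular radius, degrees) and `lit`
#'   (radiance applied to all bands); source pixels take
#'   `max(scene, source)`.
#' @param name Scene name.
#' @param seed Integer seed for the texture.
#' @return An object of class `synth_scene_spec`.
#' @export
synth_scene_spec <- function(profile, sigma = 0.25, sources = list(),
                             name = "synthetic", seed = 1L) {
  profile <- as_tibble(profile)
  needed <- c("elevation", "red", "green", "blue")
  if (!all(needed %in% names(profile))) {
    abort("`profile` needs columns elevation, red, green, blue.")
  }
  if (any(!is.finite(as.matrix(profile[needed])))) {
    abort("`profile` values must be finite.")
  }
  if (sigma < 0) abort("`sigma` must be >= 0.")
  structure(
    list(profile = profile[order(profile$elevation), ], sigma = sigma,
         sources = sources, name = name, seed = as.integer(seed)),
    class = "synth_scene_spec"
  )
}

# Shared relative elevation shape for the presets: brighter sky, a dark
# band at the horizon, and a ground dimmer than the sky. Slight red/blue
# asymmetry above vs below the horizon mimics blue sky over reddish ground.
preset_shape <- function(level, sigma, name, seed) {
  el <- c(-90, -15, 0, 15, 90)
  base <- c(-0.35, -0.15, -0.50, 0.25, 0.60)
  synth_scene_spec(
    profile = tibble(
      elevation = el,
      red = level + base + c(0.10, 0.10, 0.00, -0.15, -0.25),
      green = level + base,
      blue = level + base + c(-0.15, -0.10, 0.00, 0.15, 0.20)
    ),
    sigma = sigma, name = name, seed = seed
  )
}

#' Preset synthetic scenes at natural radiance regimes
#'
#' Presets anchored to the radiance regimes of natural and artificial
#' light environments: outdoor sunlit scenes sit at 16-18 lit, overcast
#' at 15-16 lit, indoor lighting at 13-16 lit, moonlight around 11 lit
#' and starlight around 9 lit. All presets share the same relative
#' elevation shape (bright sky, dark horizon band, intermediate ground);
#' "overcast" has a much narrower texture, reproducing its massive
#' reduction in contrast-span.
#'
#' @param name One of "sunlight", "overcast", "indoor", "moonlight",
#'   "starlight".
#' @param seed Integer seed for the texture.
#' @return A [synth_scene_spec()].
#' @export
synth_preset <- function(name = c("sunlight", "overcast", "indoor",
                                  "moonlight", "starlight"),
                         seed = 1L) {
  name <- match.arg(name)
  cfg <- switch(name,
    sunlight = list(level = 17.0, sigma = 0.30),
    overcast = list(level = 15.6, sigma = 0.10),
    indoor = list(level = 14.0, sigma = 0.35),
    moonlight = list(level = 11.1, sigma = 0.30),
    starlight = list(level = 9.1, sigma = 0.25)
  )
  preset_shape(cfg$level, cfg$sigma, name, seed)
}

interp_profile <- function(spec, band, elevation) {
  approx(spec$profile$elevation, spec$profile[[band]], xout = elevation,
         rule = 2)$y
}

#' Render the ground-truth radiance field of a synthetic scene
#'
#' Builds the equirectangular radiance image described by a scene spec:
#' `radiance(elevation, azimuth, band) = 10^profile_band(elevation) *
#' 10^N(0, sigma)`, with the Gaussian lit-noise field shared across bands,
#' then point sources applied as `max(scene, source)`. Alongside the
#' image it returns the analytic per-bin ground truth the pipeline should
#' recover: the bin-centre profile value as the median (the median of a
#' log-normal is its log-centre) and `2 * 1.96 * sigma` lit as the 95%
#' contrast-span.
#'
#' @param spec A [synth_scene_spec()].
#' @param size Output side length M of the equirectangular image.
#' @param n_bins Number of elevation bins in the ground-truth table.
#' @return A list with elements `image` ([equirect_image()]) and `truth`
#'   (tibble with `bin`, `elevation`, `<band>_median` in lit per band and
#'   `span95` in lit).
#' @export
make_truth <- function(spec, size = 500, n_bins = 60) {
  if (!inherits(spec, "synth_scene_spec")) {
    abort("`spec` must be a synth_scene_spec.")
  }
  m <- as.integer(size)
  el <- equirect_elevations(m)
  az <- equirect_azimuths(m)
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(spec$seed)
  noise <- matrix(rnorm(m * m, 0, spec$sigma), m, m)
  pixels <- array(NA_real_, c(m, m, 3L))
  for (k in seq_len(3L)) {
    band <- c("red", "green", "blue")[k]
    base <- interp_profile(spec, band, el)
    pixels[, , k] <- 10^(matrix(base, m, m) + noise)
  }
  if (length(spec$sources)) {
    el_g <- matrix(rep(el, times = m), m, m)
    az_g <- matrix(rep(az, each = m), m, m)
    for (src in spec$sources) {
      gc_dist <- angular_distance(el_g, az_g, src$elevation, src$azimuth)
      hit <- gc_dist <= src$radius
      for (k in seq_len(3L)) {
        plane <- pixels[, , k]
        plane[hit] <- pmax(plane[hit], 10^src$lit)
        pixels[, , k] <- plane
      }
    }
  }
  width <- 180 / n_bins
  centers <- 90 - width * (seq_len(n_bins) - 0.5)
  truth <- tibble(
    bin = seq_len(n_bins),
    elevation = centers,
    red_median = interp_profile(spec, "red", centers),
    green_median = interp_profile(spec, "green", centers),
    blue_median = interp_profile(spec, "blue", centers),
    span95 = 2 * 1.96 * spec$sigma
  )
  truth$white_median <- log10(
    (10^truth$red_median + 10^truth$green_median + 10^truth$blue_median) / 3
  )
  list(image = equirect_image(pixels), truth = truth)
}

# great-circle angular distance in degrees
angular_distance <- function(el1, az1, el2, az2) {
  to_r <- pi / 180
  c1 <- cos(el1 * to_r); s1 <- sin(el1 * to_r)
  c2 <- cos(el2 * to_r); s2 <- sin(el2 * to_r)
  cosd <- s1 * s2 + c1 * c2 * cos((az1 - az2) * to_r)
  acos(pmin(1, pmax(-1, cosd))) / to_r
}

#' Render a ground-truth scene into a bracketed set of camera exposures
#'
#' Inverts the analysis chain: the equirectangular ground truth is
#' forward-mapped into the camera's equisolid fisheye projection
#' (nearest-neighbour), attenuated by the calibrated vignetting, scaled
#' by exposure time and gains into sensor counts, offset by the black
#' level, clipped at the white level and (optionally) quantised to
#' integer counts. The middle (0 EV) exposure is auto-exposed so the
#' scene median lands at `target_median_frac` of the usable count range,
#' unless `base_exposure` is given. Saturation in each frame occurs
#' exactly where `truth x exposure` reaches the white level.
#'
#' @param truth An [equirect_image()] holding ground-truth radiances
#'   (e.g. from [make_truth()]).
#' @param cal A [camera_calibration()].
#' @param ev_offsets Bracket EV offsets (default c(-3, 0, 3)).
#' @param target_median_frac Auto-exposure target as a fraction of
#'   `white_level - black_level`.
#' @param base_exposure Optional exposure time (s) of the 0 EV frame.
#' @param iso,f_number Camera settings for all frames.
#' @param quantize Round counts to integers (default TRUE).
#' @return An [exposure_bracket()] of [fisheye_exposure()]s in counts.
#' @export
render_bracket <- function(truth, cal = camera_calibration(),
                           ev_offsets = c(-3, 0, 3),
                           target_median_frac = 0.05,
                           base_exposure = NULL,
                           iso = 100, f_number = 3.5, quantize = TRUE) {
  if (!inherits(truth, "equirect_image")) {
    abort("`truth` must be an equirect_image.")
  }
  validate_calibration(cal)
  m <- dim(truth$pixels)[1]
  r_px <- cal$projection$radius_px
  ctr <- cal$projection$center_xy
  w <- as.integer(ceiling(ctr[1] + r_px - 0.5))
  h <- as.integer(ceiling(ctr[2] + r_px - 0.5))
  x <- matrix(rep(seq_len(w), each = h), h, w)
  y <- matrix(rep(seq_len(h), times = w), h, w)
  dirs <- image_point_to_direction(x, y, ctr, r_px)
  inside <- matrix(dirs$valid, h, w)
  ri <- pmin(pmax(ceiling((90 - dirs$elevation) / 180 * m), 1L), m)
  ci <- pmin(pmax(ceiling((dirs$azimuth + 90) / 180 * m), 1L), m)
  ri[!dirs$valid] <- 1L
  ci[!dirs$valid] <- 1L
  idx <- cbind(ri, ci)
  theta <- matrix(dirs$theta, h, w)
  v <- vignetting_at(cal, ifelse(is.na(theta), 0, theta), f_number)
  gain <- iso_gain(cal, iso) * aperture_gain(cal, f_number)
  chans <- c("red", "green", "blue")

  scene <- array(0, c(h, w, 3L)) # radiance attenuated by vignetting
  for (k in seq_len(3L)) {
    plane_vals <- truth$pixels[, , k][idx]
    plane <- matrix(plane_vals, h, w) * v
    plane[!inside] <- 0
    scene[, , k] <- plane
  }

  if (is.null(base_exposure)) {
    med_rate <- median(unlist(lapply(seq_len(3L), function(k) {
      pl <- scene[, , k][inside] / cal$channels[[chans[k]]]
      pl
    })))
    if (!is.finite(med_rate) || med_rate <= 0) {
      abort("Scene median radiance is zero; supply `base_exposure` explicitly.")
    }
    span <- cal$white_level - cal$black_level
    base_exposure <- target_median_frac * span / med_rate
  }

  exposures <- lapply(ev_offsets, function(ev) {
    t_i <- base_exposure * ev_to_factor(ev)
    counts <- array(0, c(h, w, 3L))
    for (k in seq_len(3L)) {
      c_k <- scene[, , k] * t_i * gain / cal$channels[[chans[k]]] +
        cal$black_level
      counts[, , k] <- pmin(c_k, cal$white_level)
    }
    if (quantize) counts <- round(counts)
    fisheye_exposure(counts, exposure_time = t_i, iso = iso,
                     f_number = f_number, ev_offset = ev,
                     center = ctr, radius_px = r_px, unit = "counts")
  })
  exposure_bracket(exposures)
}

#' Read and write synthetic scene specifications
#'
#' Scene specs are serialised as JSON documents with keys `profile`
#' (records of elevation/red/green/blue), `sigma`, `sources`, `name` and
#' `seed`.
#'
#' @param path Path to a JSON scene-spec file.
#' @param spec A [synth_scene_spec()].
#' @return `read_scene_spec()` returns a `synth_scene_spec`;
#'   `write_scene_spec()` returns `path` invisibly.
#' @export
read_scene_spec <- function(path) {
  if (!file.exists(path)) abort(paste0("Scene spec not found: ", path))
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  sources <- raw$sources
  if (is.data.frame(sources)) {
    sources <- lapply(seq_len(nrow(sources)), function(i) as.list(sources[i, ]))
  } else if (is.null(sources)) {
    sources <- list()
  }
  synth_scene_spec(profile = as_tibble(raw$profile), sigma = raw$sigma,
                   sources = sources, name = raw$name, seed = raw$seed)
}

#' @rdname read_scene_spec
#' @export
write_scene_spec <- function(spec, path) {
  if (!inherits(spec, "synth_scene_spec")) {
    abort("`spec` must be a synth_scene_spec.")
  }
  jsonlite::write_json(
    list(profile = spec$profile, sigma = spec$sigma, sources = spec$sources,
         name = spec$name, seed = spec$seed),
    path, auto_unbox = TRUE, digits = NA, dataframe = "rows", pretty = TRUE
  )
  invisible(path)
}
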