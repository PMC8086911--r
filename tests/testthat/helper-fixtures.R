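# Shared fixtures: a small fast camera for unit tests and a helper that
# runs the full render -> disk -> analyse chain.

small_calibration <- function(radius_px = 60) {
  camera_calibration(
    projection = list(model = "equisolid",
                      center_xy = c(radius_px + 0.5, radius_px + 0.5),
                      radius_px = radius_px)
  )
}

# Constant-radiance equirect image (linear radiance `value` in all bands).
constant_image <- function(value, m = 24) {
  equirect_image(array(value, c(m, m, 3L)))
}

# Equirect image with independent log-normal pixels: lit ~ N(mu, sigma),
# shared across bands.
lognormal_image <- function(mu, sigma, m = 120, seed = 1) {
  withr::with_seed(seed, {
    noise <- matrix(rnorm(m * m, 0, sigma), m, m)
  })
  px <- array(10^(mu + as.vector(noise)), c(m, m, 3L))
  equirect_image(px)
}

# Render a truth image through the camera, write to a temp dir, read back
# and analyse; returns the elf_scene.
analyse_rendered <- function(truth_image, cal, ...) {
  bracket <- render_bracket(truth_image, cal, ...)
  dir <- withr::local_tempdir(.local_envir = parent.frame())
  write_bracket(bracket, dir, name = "fix")
  elf_scene(dir, cal = cal)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Independent sort-based type-7 quantile (manual interpolation between
# order statistics); deliberately not stats::quantile.
brute_quantile <- function(x, p) {
  v <- sort(x)
  n <- length(v)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  v[lo] + (h - lo) * (v[hi] - v[lo])
}
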