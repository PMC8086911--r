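test_that("lit conversions are exact powers of ten and round-trip", {
  expect_equal(to_lit(1e11), 11)
  expect_equal(to_lit(10^16.5), 16.5)
  expect_equal(to_lit(1), 0)
  expect_equal(from_lit(11), 1e11)
  # round trip across the full natural range
  L <- 10^seq(5, 20, length.out = 200)
  expect_true(all(abs(from_lit(to_lit(L)) - L) / L < 1e-12))
  expect_error(to_lit(c(1, NaN)), "non-finite")
  expect_error(to_lit(0), "<= 0")
})

test_that("lit spans map to linear factors and percent changes", {
  expect_equal(lit_span_to_percent(0.01), 2.3, tolerance = 0.05 / 2.3)
  expect_equal(lit_span_to_factor(2), 100)
  expect_equal(lit_span_to_factor(0), 1)
  expect_equal(lit_span_to_percent(0), 0)
  # log additivity
  a <- c(0.3, -1.2, 2.5)
  b <- c(0.7, 0.2, -2.5)
  expect_equal(lit_span_to_factor(a + b),
               lit_span_to_factor(a) * lit_span_to_factor(b))
})

test_that("EV steps are factor-2 exposure changes", {
  expect_identical(ev_to_factor(c(3, 6, 0)), c(8, 64, 1))
  expect_equal(ev_to_factor(-3), 1 / 8)
})

test_that("photon energy scales inversely with wavelength", {
  expect_equal(photon_energy_percent_diff(400, 700), 75)
  expect_equal(photon_energy_percent_diff(500, 500), 0)
  # E = hc/lambda halves when the wavelength doubles
  expect_equal(photon_energy_percent_diff(350, 700), 100)
  expect_error(photon_energy_percent_diff(-1, 500), "positive")
})

test_that("energy radiance converts to photon radiance via hc/lambda", {
  # independent oracle: direct arithmetic with CODATA h and c
  h <- 6.62607015e-34
  c0 <- 299792458
  expected <- 1.0 * 500e-9 / (h * c0)
  got <- energy_to_photon_radiance(1.0, 500)
  expect_equal(got, expected)
  expect_equal(got, 2.517e18, tolerance = 1e-3)
  expect_equal(to_lit(got), 18.4, tolerance = 0.01 / 18.4)
  expect_equal(energy_to_photon_radiance(0, 423), 0)
  # linearity
  expect_equal(energy_to_photon_radiance(2, 555),
               2 * energy_to_photon_radiance(1, 555))
  expect_error(energy_to_photon_radiance(1, 0), "positive")
})

test_that("spectral bands are the contiguous 100-nm slots", {
  bands <- spectral_bands()
  expect_setequal(bands$band, c("red", "green", "blue", "white"))
  expect_equal(bands$lambda_min[bands$band == "blue"], 400)
  expect_equal(bands$lambda_max[bands$band == "red"], 700)
  rgb <- dplyr::filter(bands, band != "white") |>
    dplyr::arrange(lambda_min)
  expect_equal(rgb$lambda_max[-3], rgb$lambda_min[-1]) # contiguous
})

test_that("counts convert to radiance by the calibration model", {
  cal <- camera_calibration(
    channels = list(red = 1e12, green = 1e12, blue = 1e12),
    black_level = 0, white_level = 10000,
    iso_gain = list(`100` = 1), aperture_gain = list(`3.5` = 1)
  )
  counts <- matrix(500, 2, 2)
  out <- counts_to_radiance(counts, exposure_time = 0.01, iso = 100,
                            f_number = 3.5, cal = cal, channel = "green")
  expect_equal(out$radiance, matrix(5e16, 2, 2))
  expect_false(any(out$saturated))

  # black level maps to zero pre-clamp, then to the dark-noise floor
  cal2 <- camera_calibration()
  counts2 <- matrix(c(cal2$black_level, cal2$black_level + 100), 1, 2)
  out2 <- counts_to_radiance(counts2, 0.1, 100, 3.5, cal2, channel = "red")
  expect_equal(out2$radiance[1], 1e-3 * out2$radiance[2])

  # reciprocity: doubling the exposure time halves the radiance
  out_t1 <- counts_to_radiance(matrix(800, 1, 1), 0.02, 100, 3.5, cal,
                               channel = "red")
  out_t2 <- counts_to_radiance(matrix(800, 1, 1), 0.04, 100, 3.5, cal,
                               channel = "red")
  expect_equal(out_t2$radiance, out_t1$radiance / 2)

  # saturation flagged at 99% of the white level
  sat <- counts_to_radiance(matrix(c(9899, 9900), 1, 2), 0.01, 100, 3.5,
                            cal, channel = "red")
  expect_identical(as.vector(sat$saturated), c(FALSE, TRUE))

  expect_error(
    counts_to_radiance(counts, 0.01, 100, 3.5, cal, channel = "uv"),
    "uv"
  )
})

test_that("counts-to-radiance is linear in counts and inverse in time", {
  cal <- camera_calibration(black_level = 100, white_level = 60000)
  withr::with_seed(42, {
    for (i in 1:5) {
      counts <- matrix(runif(16, 200, 5000), 4, 4)
      t1 <- runif(1, 0.001, 1)
      a <- counts_to_radiance(counts, t1, 100, 3.5, cal, channel = "blue")
      b <- counts_to_radiance(2 * counts - 100, t1, 100, 3.5, cal,
                              channel = "blue")
      expect_equal(b$radiance, 2 * a$radiance)
      d <- counts_to_radiance(counts, 5 * t1, 100, 3.5, cal, channel = "blue")
      expect_equal(d$radiance, a$radiance / 5)
    }
  })
})

test_that("vignetting correction inverts a known fall-off", {
  cal <- camera_calibration()
  theta <- matrix(seq(0, 90, length.out = 64), 8, 8)

  # a V == 1 table leaves the image unchanged
  cal_flat <- camera_calibration(vignetting = list(`3.5` = rep(1, 10)))
  img <- matrix(7e14, 8, 8)
  expect_equal(vignetting_correct(img, theta, cal_flat, 3.5), img)

  # apply a smooth analytic fall-off, correct with its 10-degree table
  v_fun <- function(th) 1 - 0.25 * (th / 90)^2
  cal_v <- camera_calibration(
    vignetting = list(`3.5` = v_fun(seq(0, 90, by = 10)))
  )
  flat <- matrix(1e15, 8, 8)
  attenuated <- flat * v_fun(theta)
  corrected <- vignetting_correct(attenuated, theta, cal_v, 3.5)
  expect_true(all(abs(corrected - flat) / flat < 0.01))

  # interpolation midpoint between the 0- and 10-degree entries
  cal_mid <- camera_calibration(
    vignetting = list(`3.5` = c(1, 0.9, rep(0.9, 8)))
  )
  out <- vignetting_correct(matrix(1, 1, 1), matrix(5, 1, 1), cal_mid, 3.5)
  expect_equal(out[1, 1], 1 / 0.95)

  expect_error(vignetting_correct(img, theta + 10, cal, 3.5), "90")
  expect_warning(vignetting_correct(img, theta, cal, 5.6), "nearest")
})

test_that("vignetting apply-then-correct round-trips any positive table", {
  withr::with_seed(7, {
    for (i in 1:5) {
      v_tab <- c(1, sort(runif(9, 0.3, 1), decreasing = TRUE))
      cal <- camera_calibration(vignetting = list(`3.5` = v_tab))
      theta <- matrix(runif(100, 0, 90), 10, 10)
      img <- matrix(10^runif(100, 10, 18), 10, 10)
      v <- elfr:::vignetting_at(cal, theta, 3.5)
      rec <- vignetting_correct(img * v, theta, cal, 3.5)
      expect_true(all(abs(rec - img) / img < 0.01))
    }
  })
})

test_that("white band is the per-nm average of the colour slots", {
  expect_equal(white_from_rgb(3e15, 3e15, 3e15), 3e15)
  expect_equal(white_from_rgb(0, 0, 3e15), 1e15)
  expect_equal(to_lit(white_from_rgb(1e16, 1e16, 1e16)), 16)
  expect_error(white_from_rgb(-1, 1, 1), "non-negative")
})

test_that("calibration files round-trip through JSON with validation", {
  cal <- camera_calibration()
  path <- withr::local_tempfile(fileext = ".json")
  write_calibration(cal, path)
  back <- read_calibration(path)
  expect_equal(back$channels, cal$channels)
  expect_equal(back$vignetting, cal$vignetting)
  expect_equal(back$projection$radius_px, cal$projection$radius_px)

  expect_error(camera_calibration(black_level = 20000), "white_level")
  expect_error(
    camera_calibration(vignetting = list(`3.5` = c(0.9, rep(0.8, 9)))),
    "V\\(0\\)"
  )
  expect_error(read_calibration(withr::local_tempfile()), "not found")
})
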