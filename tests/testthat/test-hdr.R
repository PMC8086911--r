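make_equirect_exposure <- function(value_or_pixels, ev, m = 12,
                                   saturated = NULL) {
  px <- if (length(value_or_pixels) == 1L) {
    array(value_or_pixels, c(m, m, 3L))
  } else {
    value_or_pixels
  }
  im <- equirect_image(px, saturated = saturated)
  attr(im, "meta") <- list(ev_offset = ev)
  im
}

test_that("brackets order exposures by EV and validate geometry", {
  a <- make_equirect_exposure(1, ev = 3)
  b <- make_equirect_exposure(1, ev = -3)
  c0 <- make_equirect_exposure(1, ev = 0)
  br <- exposure_bracket(a, b, c0)
  expect_equal(vapply(br, elfr:::bracket_ev, numeric(1)), c(-3, 0, 3))
  expect_error(exposure_bracket(a, make_equirect_exposure(1, 3, m = 8)),
               "geometry")
  expect_error(exposure_bracket(a, make_equirect_exposure(2, 3)),
               "strictly increasing")
})

test_that("bracket normalisation matches medians to the bracket average", {
  ims <- list(
    make_equirect_exposure(0.5, ev = -3),
    make_equirect_exposure(1.0, ev = 0),
    make_equirect_exposure(2.0, ev = 3)
  )
  norm <- normalize_bracket(exposure_bracket(ims))
  # geometric mean of {0.5, 1, 2} is 1, so scales are {2, 1, 0.5}
  expect_equal(attr(norm, "scales"), c(2, 1, 0.5))
  meds <- vapply(norm, function(im) median(im$pixels), numeric(1))
  expect_equal(meds, rep(1, 3))

  # arithmetic option uses the plain mean of the medians
  norm_a <- normalize_bracket(exposure_bracket(ims), reference = "arithmetic")
  expect_equal(attr(norm_a, "scales"), (3.5 / 3) / c(0.5, 1, 2))

  # all equal medians leave scales at 1; single exposures are unchanged
  same <- exposure_bracket(list(make_equirect_exposure(4, -3),
                                make_equirect_exposure(4, 0)))
  expect_equal(attr(normalize_bracket(same), "scales"), c(1, 1))
  single <- exposure_bracket(list(make_equirect_exposure(4, 0)))
  expect_equal(normalize_bracket(single)[[1]]$pixels, single[[1]]$pixels)
})

test_that("normalisation ignores saturated pixels and drops dead frames", {
  m <- 12
  sat <- matrix(FALSE, m, m)
  sat[1:6, ] <- TRUE # half the frame saturated in one exposure
  px <- array(1, c(m, m, 3L))
  px[1:6, , ] <- 100 # bogus values under saturation
  ims <- list(
    make_equirect_exposure(px, ev = -3, saturated = sat),
    make_equirect_exposure(2, ev = 0)
  )
  norm <- normalize_bracket(exposure_bracket(ims))
  # medians computed only over mutually unsaturated pixels: {1, 2}
  expect_equal(attr(norm, "scales"), c(sqrt(2), sqrt(2) / 2))

  all_sat <- make_equirect_exposure(9, ev = 3,
                                    saturated = matrix(TRUE, m, m))
  expect_warning(
    norm2 <- normalize_bracket(exposure_bracket(list(
      make_equirect_exposure(1, -3), make_equirect_exposure(1, 0), all_sat
    ))),
    "saturated everywhere"
  )
  expect_length(norm2, 2)
})

test_that("HDR merge takes the highest unsaturated exposure per pixel", {
  m <- 6
  sat_hi <- matrix(FALSE, m, m); sat_hi[1, 1] <- TRUE
  sat_all <- matrix(FALSE, m, m); sat_all[2, 2] <- TRUE
  sat_hi2 <- sat_hi; sat_hi2[2, 2] <- TRUE
  lo <- make_equirect_exposure(array(1, c(m, m, 3L)), ev = -3,
                               saturated = sat_all)
  mid <- make_equirect_exposure(array(2, c(m, m, 3L)), ev = 0,
                                saturated = sat_hi2)
  hi <- make_equirect_exposure(array(3, c(m, m, 3L)), ev = 3,
                               saturated = sat_hi2)
  merged <- merge_hdr(exposure_bracket(list(lo, mid, hi)))
  # unsaturated everywhere -> highest EV value
  expect_equal(merged$pixels[3, 3, 1], 3)
  # saturated only in the top exposures -> next exposure down
  expect_equal(merged$pixels[1, 1, 1], 1)
  # saturated in every exposure -> lowest-EV value, flagged
  expect_equal(merged$pixels[2, 2, 1], 1)
  expect_true(merged$saturated[2, 2])
  expect_false(merged$saturated[1, 1])
})

test_that("merging identical images returns that image, in any order", {
  m <- 10
  withr::with_seed(5, {
    px <- array(10^runif(m * m * 3, 12, 15), c(m, m, 3L))
  })
  ims <- lapply(c(-3, 0, 3), function(ev) make_equirect_exposure(px, ev))
  merged <- merge_hdr(normalize_bracket(exposure_bracket(ims)))
  expect_equal(merged$pixels, px)
  # permutation invariance: the bracket sorts by EV
  perm <- merge_hdr(normalize_bracket(exposure_bracket(ims[c(2, 3, 1)])))
  expect_equal(perm$pixels, merged$pixels)
})

test_that("a 3-exposure 3-EV bracket extends dynamic range by 64", {
  # noiseless radiance ramp covering 4.5 lit with a dense value grid;
  # flat vignetting so the saturation radiance is uniform over the field
  cal <- camera_calibration(
    vignetting = list(`3.5` = rep(1, 10)),
    projection = list(model = "equisolid", center_xy = c(80.5, 80.5),
                      radius_px = 80)
  )
  m <- 160
  grid <- seq(12, 16.5, length.out = m * m)
  truth <- equirect_image(array(10^grid, c(m, m, 3L)))
  bracket <- render_bracket(truth, cal, ev_offsets = c(-3, 0, 3),
                            target_median_frac = 0.2, quantize = FALSE)
  dir <- withr::local_tempdir()
  write_bracket(bracket, dir, "ramp")
  rad <- read_bracket(dir, cal)
  remapped <- lapply(unclass(rad), remap_to_equirect)
  merged <- merge_hdr(normalize_bracket(exposure_bracket(remapped)))

  # largest unsaturated radiance: single highest-EV frame vs merged
  hi <- remapped[[3]]
  max_single <- max(hi$pixels[, , 2][!hi$saturated & hi$mask])
  max_merged <- max(merged$pixels[, , 2][!merged$saturated & merged$mask])
  ratio <- max_merged / max_single
  expect_equal(ratio, 64, tolerance = 0.05)
  # the bracket recovers truth across the extra ~1.8 lit
  expect_equal(log10(ratio), log10(64), tolerance = 0.02)
  # the single exposure did saturate inside the scene range
  expect_gt(sum(hi$saturated), 0)

  # merged values sit on the ground-truth value grid wherever the pixel
  # was recoverable; the only loss is the 1-count granularity of the
  # 16-bit files, which matters solely in the deepest shadows
  vals <- log10(merged$pixels[, , 2][!merged$saturated & merged$mask])
  step <- (16.5 - 12) / (m * m - 1)
  snapped <- 12 + step * round((vals - 12) / step)
  dev <- abs(vals - snapped)
  expect_lt(quantile(dev, 0.98, names = FALSE), log10(1.001))
  expect_lt(max(dev), log10(1.02))
})

test_that("a noiseless bracket with per-exposure saturation merges to truth", {
  # bracket built directly in radiance space: each frame clips at its own
  # saturation radiance, the merge must restore truth except where every
  # frame clipped
  m <- 40
  withr::with_seed(9, {
    truth <- array(10^runif(m * m * 3, 13, 16.5), c(m, m, 3L))
  })
  sat_levels <- 10^c(14, 15, 16) # lowest EV clips last
  frames <- lapply(seq_along(sat_levels), function(i) {
    level <- rev(sat_levels)[i]
    sat <- matrix(FALSE, m, m)
    px <- truth
    for (k in 1:3) sat <- sat | (truth[, , k] >= level)
    for (k in 1:3) px[, , k] <- pmin(px[, , k], level)
    im <- equirect_image(px, saturated = sat)
    attr(im, "meta") <- list(ev_offset = c(-3, 0, 3)[i])
    im
  })
  merged <- merge_hdr(exposure_bracket(frames))
  ok <- !merged$saturated
  for (k in 1:3) {
    expect_lt(max(abs(merged$pixels[, , k][ok] - truth[, , k][ok]) /
                    truth[, , k][ok]), 0.001)
  }
  # all-saturated pixels keep the lowest-EV (clipped) frame values, flagged
  for (k in 1:3) {
    expect_equal(merged$pixels[, , k][!ok], pmin(truth[, , k], 1e16)[!ok])
  }
  expect_equal(sum(merged$saturated),
               sum(truth[, , 1] >= 1e16 | truth[, , 2] >= 1e16 |
                     truth[, , 3] >= 1e16))
})
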