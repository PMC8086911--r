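#' Exposure bracket container
#'
#' An ordered set of radiance-converted images of the same scene taken at
#' increasing exposure (EV offsets strictly increasing), typically three
#' exposures at -3, 0 and +3 EV. Images may be equirectangular
#' ([equirect_image()] with an attached `meta` attribute) or fisheye
#' ([fisheye_exposure()]); all must share raster geometry.
#'
#' @param ... Images, or a single list of images.
#' @return An object of class `exposure_bracket` (a list of images sorted
#'   by EV offset).
#' @export
exposure_bracket <- function(...) {
  imgs <- list(...)
  if (length(imgs) == 1L && !inherits(imgs[[1]], c("equirect_image", "fisheye_exposure"))) {
    imgs <- imgs[[1]]
  }
  if (!length(imgs)) abort("A bracket needs at least one exposure.")
  evs <- vapply(imgs, bracket_ev, numeric(1))
  dims <- vapply(imgs, function(im) dim(bracket_pixels(im))[1:2], numeric(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    abort("All exposures in a bracket must share raster geometry.")
  }
  imgs <- imgs[order(evs)]
  evs <- sort(evs)
  if (length(evs) > 1L && any(diff(evs) <= 0)) {
    abort("EV offsets within a bracket must be strictly increasing.")
  }
  structure(imgs, class = "exposure_bracket")
}

bracket_ev <- function(im) {
  meta <- if (inherits(im, "fisheye_exposure")) im$meta else attr(im, "meta")
  if (is.null(meta$ev_offset)) abort("Exposure lacks an `ev_offset`.")
  meta$ev_offset
}

bracket_pixels <- function(im) im$pixels

bracket_saturated <- function(im) {
  s <- im$saturated
  if (is.null(s)) s <- matrix(FALSE, dim(im$pixels)[1], dim(im$pixels)[2])
  s
}

bracket_mask <- function(im) {
  msk <- im$mask
  if (is.null(msk)) msk <- matrix(TRUE, dim(im$pixels)[1], dim(im$pixels)[2])
  msk
}

#' @export
print.exposure_bracket <- function(x, ...) {
  cat("<exposure_bracket> ", length(x), " exposure(s), EV offsets: ",
      paste(sprintf("%+g", vapply(x, bracket_ev, numeric(1))),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Normalise exposures within a bracket
#'
#' Random inter-exposure differences (small aperture errors, light changes
#' between frames) are removed before merging: the median radiance of each
#' exposure is computed over the pixels that are valid and unsaturated in
#' every exposure, and each image is scaled so its median matches the
#' bracket average. The average is the geometric mean of the per-exposure
#' medians by default (the pipeline's statistics live in log space); an
#' arithmetic mean is available as an option. Exposures saturated
#' everywhere are excluded with a warning.
#'
#' @param bracket An [exposure_bracket()] of radiance images.
#' @param reference "geometric" (default) or "arithmetic" mean of the
#'   per-exposure medians.
#' @return The bracket with pixels rescaled; scale factors are attached as
#'   attribute `scales`.
#' @export
normalize_bracket <- function(bracket, reference = c("geometric", "arithmetic")) {
  reference <- match.arg(reference)
  if (!inherits(bracket, "exposure_bracket")) {
    abort("`bracket` must be an exposure_bracket.")
  }
  all_sat <- vapply(bracket, function(im) {
    msk <- bracket_mask(im)
    all(bracket_saturated(im)[msk])
  }, logical(1))
  if (any(all_sat)) {
    warn(paste0(sum(all_sat), " exposure(s) saturated everywhere; excluded."))
    bracket <- structure(unclass(bracket)[!all_sat], class = "exposure_bracket")
  }
  if (length(bracket) == 1L) {
    attr(bracket, "scales") <- 1
    return(bracket)
  }
  valid <- Reduce(`&`, lapply(bracket, function(im) {
    bracket_mask(im) & !bracket_saturated(im)
  }))
  if (!any(valid)) abort("No pixel is unsaturated in every exposure.")
  medians <- vapply(bracket, function(im) {
    px <- bracket_pixels(im)
    vals <- c(px[, , 1][valid], px[, , 2][valid], px[, , 3][valid])
    median(vals)
  }, numeric(1))
  ref <- if (reference == "geometric") {
    10^mean(log10(medians))
  } else {
    mean(medians)
  }
  scales <- ref / medians
  out <- lapply(seq_along(bracket), function(i) {
    im <- bracket[[i]]
    im$pixels <- im$pixels * scales[i]
    im
  })
  out <- structure(out, class = "exposure_bracket")
  attr(out, "scales") <- scales
  out
}

#' Merge a normalised bracket into one HDR radiance image
#'
#' Each output pixel takes the value it holds in the "brightest" (highest
#' EV) exposure in which it is not saturated; saturated pixel values are
#' ignored. Pixels saturated in every exposure keep the lowest-EV value
#' (itself a lower bound on the true radiance, mimicking saturation of the
#' eye) and are flagged in the output saturation mask.
#'
#' @param bracket An [exposure_bracket()] of equirectangular radiance
#'   images, normally from [normalize_bracket()].
#' @return An [equirect_image()] with a saturation mask.
#' @export
merge_hdr <- function(bracket) {
  if (!inherits(bracket, "exposure_bracket")) {
    abort("`bracket` must be an exposure_bracket.")
  }
  if (!all(vapply(bracket, inherits, logical(1), "equirect_image"))) {
    abort("merge_hdr() expects remapped (equirectangular) exposures.")
  }
  m <- dim(bracket[[1]]$pixels)[1]
  # start from the lowest EV (covers the all-saturated case), then
  # overwrite with each higher exposure where it is valid and unsaturated
  pixels <- bracket_pixels(bracket[[1]])
  chosen_sat <- bracket_saturated(bracket[[1]])
  mask <- bracket_mask(bracket[[1]])
  for (im in unclass(bracket)[-1]) {
    usable <- bracket_mask(im) & !bracket_saturated(im)
    for (k in seq_len(3L)) {
      plane <- pixels[, , k]
      src <- im$pixels[, , k]
      plane[usable] <- src[usable]
      pixels[, , k] <- plane
    }
    chosen_sat[usable] <- FALSE
    mask <- mask | bracket_mask(im)
  }
  equirect_image(pixels, mask = mask, saturated = chosen_sat & mask)
}
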