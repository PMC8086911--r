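#' Aggregate single-scene statistics into an environment description
#'
#' An environment is sampled by multiple scenes (typically 10-40 vantage
#' points). Medians and percentiles are combined across scenes by the
#' log-average x_bar = 10^((1/n) sum log10 x_i), i.e. the geometric mean:
#' brightness perception operates on a logarithmic scale, and dimmer
#' scenes (say, a cloud moved in front of the sun) still contribute
#' equally to the average. Means are log-averaged likewise; minima and
#' maxima are pooled extremes across scenes; an aggregated standard
#' deviation is not defined and is reported as missing.
#'
#' @param stats_list A list of `elf_stats` tibbles sharing the same bin
#'   structure, or a single `elf_stats`.
#' @param name Optional environment name stored with the result.
#' @return An `elf_stats` tibble (class also `elf_environment`) with
#'   attribute `n_scenes`. Aggregating a single scene is the identity.
#' @export
aggregate_scenes <- function(stats_list, name = NULL) {
  if (inherits(stats_list, "elf_stats")) stats_list <- list(stats_list)
  if (!length(stats_list)) abort("`stats_list` must contain at least one scene.")
  if (!all(vapply(stats_list, inherits, logical(1), "elf_stats"))) {
    abort("All elements of `stats_list` must be elf_stats objects.")
  }
  ref <- stats_list[[1]]
  for (s in stats_list[-1]) {
    if (nrow(s) != nrow(ref) ||
        max(abs(s$elevation - ref$elevation)) > 1e-9) {
      abort("Scenes have mismatched bin structures.")
    }
  }
  n <- length(stats_list)
  out <- ref
  log_avg_cols <- as.vector(outer(
    ELF_BANDS, c("mean", "median", "p25", "p75", "p2_5", "p97_5"),
    function(b, s) paste0(b, "_", s)
  ))
  for (col in log_avg_cols) {
    # statistics are stored in lit, so the log-average is the plain mean
    out[[col]] <- rowMeans(do.call(cbind, lapply(stats_list, `[[`, col)))
  }
  for (b in ELF_BANDS) {
    out[[paste0(b, "_min")]] <-
      do.call(pmin, lapply(stats_list, `[[`, paste0(b, "_min")))
    out[[paste0(b, "_max")]] <-
      do.call(pmax, lapply(stats_list, `[[`, paste0(b, "_max")))
    out[[paste0(b, "_std")]] <- if (n == 1L) {
      stats_list[[1]][[paste0(b, "_std")]]
    } else {
      rep(NA_real_, nrow(out)) # pooled spread across scenes is undefined
    }
  }
  out$n_pixels <- Reduce(`+`, lapply(stats_list, `[[`, "n_pixels"))
  out <- new_elf_stats(out, n_bins = attr(ref, "n_bins"),
                       n_valid_pixels = sum(out$n_pixels),
                       n_scenes = n)
  class(out) <- c("elf_environment", class(out))
  attr(out, "name") <- name
  out
}

#' Average display image of an environment
#'
#' Per-pixel geometric mean of the scene radiance images, consistent with
#' the log domain in which the statistics are aggregated. Pixels masked in
#' a scene are excluded from that pixel's mean; pixels masked everywhere
#' stay masked. The result is for display only and never feeds the
#' statistics.
#'
#' @param images A list of [equirect_image()]s with identical geometry.
#' @return An [equirect_image()].
#' @export
average_image <- function(images) {
  if (inherits(images, "equirect_image")) images <- list(images)
  if (!length(images)) abort("`images` must contain at least one image.")
  m <- dim(images[[1]]$pixels)[1]
  for (im in images) {
    if (!inherits(im, "equirect_image") || dim(im$pixels)[1] != m) {
      abort("All images must be equirect_images with identical geometry.")
    }
  }
  count <- Reduce(`+`, lapply(images, function(im) im$mask * 1))
  pixels <- array(NA_real_, c(m, m, 3L))
  for (k in seq_len(3L)) {
    acc <- matrix(0, m, m)
    for (im in images) {
      plane <- log10(im$pixels[, , k])
      plane[!im$mask] <- 0
      acc <- acc + plane
    }
    plane <- 10^(acc / pmax(count, 1))
    plane[count == 0] <- NA_real_
    pixels[, , k] <- plane
  }
  sat <- Reduce(`|`, lapply(images, function(im) im$saturated & im$mask))
  equirect_image(pixels, mask = count > 0, saturated = sat)
}
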