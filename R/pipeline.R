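#' Analyse one scene from a bracketed exposure set
#'
#' Runs the full single-scene chain: each radiance fisheye exposure is
#' remapped to the equirectangular grid, the bracket is normalised
#' (median-matched across exposures) and merged into one HDR radiance
#' image, and per-elevation-bin statistics are computed.
#'
#' @param bracket An [exposure_bracket()] of radiance
#'   [fisheye_exposure()]s (e.g. from [read_bracket()]), or a directory /
#'   file paths accepted by [read_bracket()].
#' @param cal A [camera_calibration()]; required when `bracket` is a path.
#' @param n_bins Number of elevation bins (default 60).
#' @param size Equirectangular output side length; default twice the
#'   image-circle radius.
#' @param reference Bracket-normalisation average, "geometric" or
#'   "arithmetic".
#' @return An object of class `elf_scene`: a list with `image`
#'   ([equirect_image()]), `stats` (`elf_stats`) and `summary`
#'   ([simplified_summary()]).
#' @export
elf_scene <- function(bracket, cal = NULL, n_bins = 60, size = NULL,
                      reference = "geometric") {
  if (is.character(bracket)) {
    if (is.null(cal)) abort("`cal` is required when reading from disk.")
    bracket <- read_bracket(bracket, cal)
  }
  if (!inherits(bracket, "exposure_bracket")) {
    abort("`bracket` must be an exposure_bracket or paths to one.")
  }
  remapped <- lapply(unclass(bracket), function(exp) {
    if (inherits(exp, "fisheye_exposure")) {
      if (identical(exp$unit, "counts")) {
        abort("Exposures must be radiance-converted before analysis.")
      }
      im <- remap_to_equirect(exp, size = size)
    } else {
      im <- exp
    }
    im
  })
  merged <- merge_hdr(normalize_bracket(exposure_bracket(remapped),
                                        reference = reference))
  stats <- bin_statistics(merged, n_bins = n_bins)
  structure(
    list(image = merged, stats = stats, summary = simplified_summary(stats)),
    class = "elf_scene"
  )
}

#' @export
print.elf_scene <- function(x, ...) {
  cat("<elf_scene>\n")
  print(x$image)
  cat("  overall white median:",
      sprintf("%.2f lit", median(x$stats$white_median, na.rm = TRUE)), "\n")
  invisible(x)
}

#' Describe an environment from multiple scenes
#'
#' Aggregates several analysed scenes into one environment description:
#' statistics are combined with [aggregate_scenes()] (log-averages of
#' medians and percentiles) and the display image with [average_image()].
#'
#' @param scenes A list of `elf_scene` objects (from [elf_scene()]).
#' @param name Environment name.
#' @return An object of class `elf_environment_result`: a list with
#'   `stats` (aggregated, class `elf_environment`), `image` (average
#'   [equirect_image()]), `summary` and `n_scenes`.
#' @export
elf_environment <- function(scenes, name = "environment") {
  if (inherits(scenes, "elf_scene")) scenes <- list(scenes)
  if (!length(scenes) || !all(vapply(scenes, inherits, logical(1), "elf_scene"))) {
    abort("`scenes` must be a list of elf_scene objects.")
  }
  stats <- aggregate_scenes(lapply(scenes, `[[`, "stats"), name = name)
  image <- average_image(lapply(scenes, `[[`, "image"))
  structure(
    list(stats = stats, image = image,
         summary = simplified_summary(stats),
         n_scenes = length(scenes), name = name),
    class = c("elf_environment_result", "elf_scene")
  )
}

#' @export
print.elf_environment_result <- function(x, ...) {
  cat("<elf_environment> '", x$name, "', ", x$n_scenes, " scene(s)\n",
      sep = "")
  print(x$image)
  invisible(x)
}
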