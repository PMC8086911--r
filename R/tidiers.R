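#' Tidy per-bin statistics into long form
#'
#' Pivots an `elf_stats` table into one row per bin, band and statistic —
#' convenient for dplyr/ggplot2 work.
#'
#' @param x An `elf_stats` tibble.
#' @param ... Unused.
#' @return A tibble with columns `bin`, `elevation`, `band`, `statistic`
#'   and `value` (lit, except `std` which is linear radiance).
#' @method tidy elf_stats
#' @export
tidy.elf_stats <- function(x, ...) {
  long <- tidyr::pivot_longer(
    as_tibble(x),
    cols = dplyr::matches("^(white|red|green|blue)_"),
    names_to = c("band", "statistic"),
    names_pattern = "^([a-z]+)_(.+)$",
    values_to = "value"
  )
  dplyr::select(long, "bin", "elevation", "band", "statistic", "value")
}

#' One-row summary of a scene or environment statistics table
#'
#' @param x An `elf_stats` tibble.
#' @param ... Unused.
#' @return A one-row tibble: `n_bins`, `n_scenes`, `n_valid_pixels`,
#'   overall white median (lit, across bins), and the mean 50% and 95%
#'   white contrast-spans.
#' @method glance elf_stats
#' @export
glance.elf_stats <- function(x, ...) {
  tibble(
    n_bins = attr(x, "n_bins"),
    n_scenes = attr(x, "n_scenes") %||% 1L,
    n_valid_pixels = attr(x, "n_valid_pixels"),
    white_median_lit = median(x$white_median, na.rm = TRUE),
    mean_span50_lit = mean(x$white_p75 - x$white_p25, na.rm = TRUE),
    mean_span95_lit = mean(x$white_p97_5 - x$white_p2_5, na.rm = TRUE)
  )
}

#' @rdname tidy.elf_stats
#' @method tidy elf_scene
#' @export
tidy.elf_scene <- function(x, ...) tidy(x$stats, ...)

#' @rdname glance.elf_stats
#' @method glance elf_scene
#' @export
glance.elf_scene <- function(x, ...) glance(x$stats, ...)
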