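ELF_BANDS <- c("white", "red", "green", "blue")
ELF_STATS <- c("mean", "std", "median", "p25", "p75", "p2_5", "p97_5",
               "min", "max")

#' Per-elevation-bin radiance statistics
#'
#' Slices an equirectangular radiance image into elevation bins (3 degrees
#' wide by default, 60 bins from +90 down to -90) and computes, for each
#' bin and each of the white, red, green and blue bands, nine statistics:
#' mean, standard deviation, median, 25th/75th and 2.5th/97.5th
#' percentiles, minimum and maximum. The white band is formed per pixel as
#' the per-nm average of the three colour bands before binning. Order
#' statistics are computed on the linear pixel population and then
#' converted to lit (a monotone transform, so identical to computing them
#' on logs); the mean is computed on linear radiances and converted to
#' lit; the standard deviation is kept in linear radiance units since a
#' log-width of a linear spread is ill-defined.
#'
#' Rows are assigned to bins by their centre elevation, using half-open
#' intervals `[lo, hi)` with the top bin closed at +90. Percentiles use
#' linear interpolation between closest order statistics (type 7). Bins
#' with no valid pixels get missing values, not zeros. The median is used
#' as the typical radiance because it is robust to strong light sources
#' covering few pixels.
#'
#' @param image An [equirect_image()] of linear photon radiances.
#' @param n_bins Number of elevation bins (default 60, i.e. 3-degree bins).
#' @return A tibble of class `elf_stats` with one row per bin: `bin`,
#'   `elevation` (bin-centre, degrees), `n_pixels`, and 36 statistic
#'   columns named `<band>_<stat>` for band in white/red/green/blue and
#'   stat in mean/std/median/p25/p75/p2_5/p97_5/min/max. All values are in
#'   lit except `<band>_std` (linear radiance).
#' @export
bin_statistics <- function(image, n_bins = 60) {
  if (!inherits(image, "equirect_image")) {
    abort("`image` must be an equirect_image.")
  }
  n_bins <- as.integer(n_bins)
  if (n_bins < 1L) abort("`n_bins` must be >= 1.")
  m <- dim(image$pixels)[1]
  el <- equirect_elevations(m)
  width <- 180 / n_bins
  # half-open [lo, hi), top bin closed at +90: row centres are never
  # exactly +90, so ceiling() indexing from the top realises this rule
  bin_of_row <- pmin(pmax(ceiling((90 - el) / width), 1L), n_bins)
  centers <- 90 - width * (seq_len(n_bins) - 0.5)

  r <- image$pixels[, , 1]
  g <- image$pixels[, , 2]
  b <- image$pixels[, , 3]
  w <- white_from_rgb(r, g, b)
  mask <- image$mask

  rows_by_bin <- split(seq_len(m), bin_of_row)
  stat_block <- function(values) {
    if (!length(values)) {
      return(setNames(rep(NA_real_, length(ELF_STATS)), ELF_STATS))
    }
    q <- quantile(values, c(0.025, 0.25, 0.5, 0.75, 0.975),
                  names = FALSE, type = 7)
    c(mean = log10(mean(values)),
      std = sd(values),
      median = log10(q[3]),
      p25 = log10(q[2]), p75 = log10(q[4]),
      p2_5 = log10(q[1]), p97_5 = log10(q[5]),
      min = log10(min(values)), max = log10(max(values)))
  }

  out <- vector("list", n_bins)
  n_pixels <- integer(n_bins)
  bands <- list(white = w, red = r, green = g, blue = b)
  for (i in seq_len(n_bins)) {
    rows <- rows_by_bin[[as.character(i)]]
    vals <- lapply(bands, function(plane) {
      if (is.null(rows)) return(numeric(0))
      sub <- plane[rows, , drop = FALSE]
      sub[mask[rows, , drop = FALSE]]
    })
    n_pixels[i] <- length(vals$white)
    blocks <- lapply(vals, stat_block)
    row_vals <- unlist(lapply(ELF_BANDS, function(bn) {
      setNames(blocks[[bn]], paste0(bn, "_", ELF_STATS))
    }))
    out[[i]] <- row_vals
  }
  res <- as_tibble(do.call(rbind, out))
  res <- dplyr::bind_cols(
    tibble(bin = seq_len(n_bins), elevation = centers, n_pixels = n_pixels),
    res
  )
  new_elf_stats(res, n_bins = n_bins,
                n_valid_pixels = sum(mask))
}

new_elf_stats <- function(data, n_bins, n_valid_pixels = NA_integer_,
                          n_scenes = 1L) {
  structure(
    data,
    class = c("elf_stats", class(tibble())),
    n_bins = n_bins,
    n_valid_pixels = n_valid_pixels,
    n_scenes = n_scenes
  )
}

#' Contrast-span widths per elevation bin
#'
#' The contrast-span is the width, in lit, of the radiance interval
#' containing 50% (25th to 75th percentile) or 95% (2.5th to 97.5th
#' percentile) of a bin's pixel radiances. It quantifies the visual
#' contrast available at each elevation angle.
#'
#' @param stats An `elf_stats` tibble from [bin_statistics()].
#' @param level 50 or 95.
#' @return A tibble with columns `elevation`, `band` and `span` (lit).
#' @export
contrast_span <- function(stats, level) {
  if (!inherits(stats, "elf_stats")) abort("`stats` must be an elf_stats.")
  if (!level %in% c(50, 95)) {
    abort("`level` must be 50 or 95.")
  }
  lo <- if (level == 50) "p25" else "p2_5"
  hi <- if (level == 50) "p75" else "p97_5"
  purrr::map_dfr(ELF_BANDS, function(bn) {
    tibble(
      elevation = stats$elevation,
      band = bn,
      span = stats[[paste0(bn, "_", hi)]] - stats[[paste0(bn, "_", lo)]]
    )
  })
}

#' Check robustness of bin medians to small bright regions
#'
#' Verification utility: replaces a fraction of each bin's pixels with
#' strongly saturating values and checks that the bin medians move by less
#' than one quantile step of the original pixel population. This is the
#' property that motivates using medians rather than means: point sources
#' covering a small part of the environment barely affect the reported
#' typical radiance.
#'
#' @param image An [equirect_image()].
#' @param fraction Fraction of pixels to replace, in `[0, 0.5)`.
#' @param seed Seed controlling which pixels are replaced.
#' @return TRUE if all white-band bin medians stay within one quantile
#'   step, FALSE otherwise.
#' @export
median_robustness_check <- function(image, fraction, seed = 1L) {
  if (fraction < 0 || fraction >= 0.5) abort("`fraction` must be in [0, 0.5).")
  base <- bin_statistics(image)
  perturbed <- image
  m <- dim(image$pixels)[1]
  hot <- 10 * max(image$pixels, na.rm = TRUE)
  if (fraction > 0) {
    old <- .Random.seed_get()
    on.exit(.Random.seed_set(old), add = TRUE)
    set.seed(seed)
    n_rep <- ceiling(fraction * m * m)
    idx <- sample.int(m * m, n_rep)
    for (k in seq_len(3L)) {
      plane <- perturbed$pixels[, , k]
      plane[idx] <- hot
      perturbed$pixels[, , k] <- plane
    }
  }
  new <- bin_statistics(perturbed)
  # one quantile step: the gap between the median and the quantile one
  # population step away, bounded below by the p25..p75 spacing density
  n_ok <- base$n_pixels > 0
  step <- (base$white_p75 - base$white_p25) / 2 +
    .Machine$double.eps
  delta <- abs(new$white_median - base$white_median)
  all(delta[n_ok] <= pmax(step[n_ok], 1e-9))
}

.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

.Random.seed_set <- function(seed) {
  if (!is.null(seed)) assign(".Random.seed", seed, envir = globalenv())
}

#' Simplified upper/lower-field summary
#'
#' Condenses the per-bin statistics into the two-row summary used for
#' quick comparison of light environments: for the upper field (+10 to
#' +90 degrees) and the lower field (-10 to -90 degrees), the typical
#' white radiance (geometric mean, with equal bin weight, of the bin
#' medians), the 95% contrast-span (difference of the geometric-mean
#' upper and lower percentile bounds) and the relative red/green/blue
#' contributions in percent (linear per-field mean radiance of each
#' colour band divided by their sum). The horizontal band (+/-10 degrees)
#' is ignored as less informative. Bins are assigned to a field by bin
#' centre.
#'
#' @param stats An `elf_stats` tibble from [bin_statistics()].
#' @return A tibble of class `elf_summary` with columns `field`,
#'   `median_lit`, `span95_lit`, `red_pct`, `green_pct`, `blue_pct`.
#' @export
simplified_summary <- function(stats) {
  if (!inherits(stats, "elf_stats")) abort("`stats` must be an elf_stats.")
  field_rows <- list(
    upper = which(stats$elevation > 10),
    lower = which(stats$elevation < -10)
  )
  out <- purrr::map_dfr(names(field_rows), function(f) {
    rows <- field_rows[[f]]
    s <- stats[rows, ]
    # geometric mean over bins = arithmetic mean in log (lit) space
    med <- mean(s$white_median)
    span <- mean(s$white_p97_5) - mean(s$white_p2_5)
    lin <- vapply(c("red", "green", "blue"), function(bn) {
      mean(10^s[[paste0(bn, "_median")]])
    }, numeric(1))
    pct <- 100 * lin / sum(lin)
    tibble(field = f, median_lit = med, span95_lit = span,
           red_pct = pct[["red"]], green_pct = pct[["green"]],
           blue_pct = pct[["blue"]])
  })
  structure(out, class = c("elf_summary", class(tibble())))
}
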