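#' Write a bracket of synthetic exposures to disk
#'
#' Each exposure is written as an uncompressed 16-bit linear TIFF of raw
#' counts plus a JSON sidecar with the exposure metadata (exposure_time,
#' iso, f_number, ev_offset, image-circle geometry). This is the primary
#' interchange format of the pipeline; camera raw files are expected to
#' be converted to linear TIFF upstream.
#'
#' @param bracket An [exposure_bracket()] of [fisheye_exposure()]s in
#'   counts.
#' @param dir Output directory (created if needed).
#' @param name Base name; files become `<name>_ev<EV>.tif/.json`.
#' @return Character vector of TIFF paths, invisibly.
#' @export
write_bracket <- function(bracket, dir, name = "scene") {
  if (!inherits(bracket, "exposure_bracket")) {
    abort("`bracket` must be an exposure_bracket.")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(bracket, function(exp) {
    ev <- exp$meta$ev_offset
    tag <- sprintf("%s_ev%+03d", name, round(ev))
    tif <- file.path(dir, paste0(tag, ".tif"))
    tiff::writeTIFF(exp$pixels / 65535, tif, bits.per.sample = 16L,
                    compression = "none")
    jsonlite::write_json(
      c(exp$meta, list(center_xy = exp$center, radius_px = exp$radius_px,
                       model = exp$model)),
      file.path(dir, paste0(tag, ".json")), auto_unbox = TRUE, digits = NA,
      pretty = TRUE
    )
    tif
  }, character(1))
  invisible(paths)
}

#' Read a bracketed exposure set and convert it to radiance
#'
#' Reads linear 16-bit TIFF exposures with JSON metadata sidecars,
#' converts counts to photon radiance with the calibration, applies the
#' vignetting correction in fisheye space (where the off-axis angle is
#' native), and returns a bracket ordered by EV offset. 8-bit input is
#' rejected: the pipeline requires linear high-bit-depth data.
#'
#' @param paths A directory containing `.tif` + `.json` pairs, or a
#'   character vector of TIFF paths (sidecars looked up by basename).
#' @param cal A [camera_calibration()].
#' @return An [exposure_bracket()] of radiance [fisheye_exposure()]s with
#'   per-pixel saturation masks.
#' @export
read_bracket <- function(paths, cal) {
  validate_calibration(cal)
  if (length(paths) == 1L && dir.exists(paths)) {
    paths <- sort(list.files(paths, pattern = "\\.tiff?$", full.names = TRUE))
  }
  if (!length(paths)) abort("No TIFF exposures found.")
  exposures <- lapply(paths, function(tif) {
    sidecar <- sub("\\.tiff?$", ".json", tif)
    if (!file.exists(sidecar)) {
      abort(paste0("Missing metadata sidecar for ", tif))
    }
    meta <- jsonlite::fromJSON(sidecar)
    for (field in c("exposure_time", "iso", "f_number", "ev_offset")) {
      if (is.null(meta[[field]])) {
        abort(paste0("Sidecar ", sidecar, " lacks required field `",
                     field, "`."))
      }
    }
    img <- tiff::readTIFF(tif, info = TRUE)
    bits <- attr(img, "bits.per.sample")
    if (!is.null(bits) && bits < 16) {
      abort(paste0(tif, " is ", bits, "-bit; linear 16-bit data required."))
    }
    # RGB payloads come back normalised to [0, 1]; recover integer counts
    counts <- array(round(as.numeric(img) * 65535), dim(img))
    conv <- counts_to_radiance(counts, exposure_time = meta$exposure_time,
                               iso = meta$iso, f_number = meta$f_number,
                               cal = cal)
    exp <- fisheye_exposure(
      conv$radiance, exposure_time = meta$exposure_time, iso = meta$iso,
      f_number = meta$f_number, ev_offset = meta$ev_offset,
      center = if (!is.null(meta$center_xy)) as.numeric(meta$center_xy) else
        cal$projection$center_xy,
      radius_px = if (!is.null(meta$radius_px)) meta$radius_px else
        cal$projection$radius_px,
      unit = "radiance", saturated = conv$saturated
    )
    theta <- fisheye_theta_map(exp)
    exp$pixels <- vignetting_correct(exp$pixels,
                                     ifelse(is.na(theta), 0, theta),
                                     cal, meta$f_number)
    exp
  })
  exposure_bracket(exposures)
}

#' Canonical results table
#'
#' Flattens an `elf_stats` object into the canonical spreadsheet layout:
#' one row per 3-degree elevation bin (60 rows) and 37 columns: the
#' bin-centre elevation followed by nine statistics (mean, standard
#' deviation, median, 25th, 75th, 2.5th, 97.5th percentile, minimum,
#' maximum) for each of the white, red, green and blue bands. All values
#' are in lit except the standard deviations, which are linear radiances.
#'
#' @param stats An `elf_stats` tibble.
#' @return A 60 x 37 tibble (for the default binning).
#' @export
stats_to_table <- function(stats) {
  if (!inherits(stats, "elf_stats")) abort("`stats` must be an elf_stats.")
  cols <- as.vector(t(outer(ELF_BANDS, ELF_STATS,
                            function(b, s) paste0(b, "_", s))))
  dplyr::select(as_tibble(stats), "elevation", dplyr::all_of(cols))
}

# ---- minimal XLSX writer -------------------------------------------------
# An xlsx file is a zip of OOXML parts. This writes numeric/string cells
# with inline strings, one worksheet per data frame. Kept deliberately
# small: no styles, no shared strings, no formulas.

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

excel_col <- function(j) {
  out <- character(length(j))
  for (i in seq_along(j)) {
    n <- j[i]
    s <- ""
    while (n > 0) {
      r <- (n - 1) %% 26
      s <- paste0(LETTERS[r + 1], s)
      n <- (n - 1) %/% 26
    }
    out[i] <- s
  }
  out
}

sheet_xml <- function(df) {
  header <- vapply(seq_along(df), function(j) {
    sprintf('<c r="%s1" t="inlineStr"><is><t>%s</t></is></c>',
            excel_col(j), xml_escape(names(df)[j]))
  }, character(1))
  rows <- c(sprintf('<row r="1">%s</row>', paste(header, collapse = "")))
  for (i in seq_len(nrow(df))) {
    cells <- vapply(seq_along(df), function(j) {
      v <- df[[j]][i]
      ref <- paste0(excel_col(j), i + 1)
      if (is.na(v)) return("") # missing cells stay empty, never zero
      if (is.numeric(v)) {
        sprintf('<c r="%s"><v>%.15g</v></c>', ref, v)
      } else {
        sprintf('<c r="%s" t="inlineStr"><is><t>%s</t></is></c>',
                ref, xml_escape(as.character(v)))
      }
    }, character(1))
    rows <- c(rows, sprintf('<row r="%d">%s</row>', i + 1,
                            paste(cells, collapse = "")))
  }
  paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
    '<worksheet xmlns="http://schemas.openxmlformats.org/spreadsheetml/2006/main">',
    "<sheetData>", paste(rows, collapse = ""), "</sheetData></worksheet>"
  )
}

#' Write data frames to a minimal XLSX workbook
#'
#' A small self-contained OOXML writer used for the results spreadsheets:
#' each data frame becomes one worksheet with a header row, numeric cells
#' at full precision and missing values as empty cells.
#'
#' @param sheets A named list of data frames (names become sheet names),
#'   or a single data frame (sheet "data").
#' @param path Output `.xlsx` path.
#' @return `path`, invisibly.
#' @export
write_xlsx_minimal <- function(sheets, path) {
  if (is.data.frame(sheets)) sheets <- list(data = sheets)
  if (is.null(names(sheets)) || any(!nzchar(names(sheets)))) {
    abort("`sheets` must be a named list of data frames.")
  }
  tmp <- tempfile("xlsx")
  dir.create(file.path(tmp, "_rels"), recursive = TRUE)
  dir.create(file.path(tmp, "xl", "_rels"), recursive = TRUE)
  dir.create(file.path(tmp, "xl", "worksheets"), recursive = TRUE)
  n <- length(sheets)
  writeLines(paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
    '<Types xmlns="http://schemas.openxmlformats.org/package/2006/content-types">',
    '<Default Extension="rels" ContentType="application/vnd.openxmlformats-package.relationships+xml"/>',
    '<Default Extension="xml" ContentType="application/xml"/>',
    '<Override PartName="/xl/workbook.xml" ContentType="application/vnd.openxmlformats-officedocument.spreadsheetml.sheet.main+xml"/>',
    paste(sprintf('<Override PartName="/xl/worksheets/sheet%d.xml" ContentType="application/vnd.openxmlformats-officedocument.spreadsheetml.worksheet+xml"/>',
                  seq_len(n)), collapse = ""),
    "</Types>"
  ), file.path(tmp, "[Content_Types].xml"))
  writeLines(paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
    '<Relationships xmlns="http://schemas.openxmlformats.org/package/2006/relationships">',
    '<Relationship Id="rId1" Type="http://schemas.openxmlformats.org/officeDocument/2006/relationships/officeDocument" Target="xl/workbook.xml"/>',
    "</Relationships>"
  ), file.path(tmp, "_rels", ".rels"))
  writeLines(paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
    '<workbook xmlns="http://schemas.openxmlformats.org/spreadsheetml/2006/main" ',
    'xmlns:r="http://schemas.openxmlformats.org/officeDocument/2006/relationships">',
    "<sheets>",
    paste(sprintf('<sheet name="%s" sheetId="%d" r:id="rId%d"/>',
                  xml_escape(names(sheets)), seq_len(n), seq_len(n)),
          collapse = ""),
    "</sheets></workbook>"
  ), file.path(tmp, "xl", "workbook.xml"))
  writeLines(paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
    '<Relationships xmlns="http://schemas.openxmlformats.org/package/2006/relationships">',
    paste(sprintf('<Relationship Id="rId%d" Type="http://schemas.openxmlformats.org/officeDocument/2006/relationships/worksheet" Target="worksheets/sheet%d.xml"/>',
                  seq_len(n), seq_len(n)), collapse = ""),
    "</Relationships>"
  ), file.path(tmp, "xl", "_rels", "workbook.xml.rels"))
  for (i in seq_len(n)) {
    writeLines(sheet_xml(as.data.frame(sheets[[i]])),
               file.path(tmp, "xl", "worksheets", sprintf("sheet%d.xml", i)))
  }
  files <- list.files(tmp, recursive = TRUE, all.files = TRUE,
                      include.dirs = FALSE)
  path <- normalizePath(path, mustWork = FALSE)
  zip::zip(path, files, root = tmp, mode = "mirror",
           include_directories = FALSE)
  unlink(tmp, recursive = TRUE)
  invisible(path)
}

#' Write scene or environment results to disk
#'
#' Serialises a completed analysis the standard way: the canonical
#' 60-row x 37-column statistics table as CSV (lit values with six
#' decimals, missing bins as empty cells) and as an XLSX workbook, plus
#' the remapped radiance image as an uncompressed 32-bit float TIFF and a
#' small tone-mapped PNG preview. Environment results gain a `metadata`
#' sheet recording the number of scenes.
#'
#' @param x An `elf_scene`, `elf_environment` result, or bare `elf_stats`.
#' @param dir Output directory (created if needed).
#' @param name Base name for all files.
#' @return Named character vector of the files written, invisibly.
#' @export
write_results <- function(x, dir, name = "elf") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  stats <- if (inherits(x, "elf_stats")) x else x$stats
  image <- if (inherits(x, "elf_scene")) x$image else attr(x, "image")
  if (!inherits(stats, "elf_stats")) {
    abort("`x` must be an elf_scene, elf_environment or elf_stats.")
  }
  tab <- stats_to_table(stats)
  files <- c()
  csv <- file.path(dir, paste0(name, ".csv"))
  tab_round <- dplyr::mutate(tab, dplyr::across(dplyr::everything(),
                                                ~ round(.x, 6)))
  write.csv(tab_round, csv, row.names = FALSE, na = "")
  files["csv"] <- csv
  sheets <- list(statistics = tab)
  n_scenes <- attr(stats, "n_scenes")
  if (inherits(stats, "elf_environment") || (!is.null(n_scenes) && n_scenes > 1)) {
    sheets$metadata <- tibble(
      key = c("n_scenes", "name"),
      value = c(as.character(n_scenes),
                as.character(attr(stats, "name") %||% name))
    )
  }
  xlsx <- file.path(dir, paste0(name, ".xlsx"))
  write_xlsx_minimal(sheets, xlsx)
  files["xlsx"] <- xlsx
  if (!is.null(image)) {
    tif <- file.path(dir, paste0(name, ".tif"))
    write_radiance_tiff(image, tif)
    files["tiff"] <- tif
    preview <- file.path(dir, paste0(name, "_preview.png"))
    png::writePNG(tonemap_image(image, max_size = 256), preview)
    files["png"] <- preview
  }
  invisible(files)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# TIFF storage encodes log10 radiance scaled by 1/ELF_TIFF_SCALE so the
# full natural range (0..30 lit) fits the [0, 1] float payload losslessly
# at 32-bit precision. Masked pixels are stored as 0.
ELF_TIFF_SCALE <- 30

#' Radiance image TIFF round trip
#'
#' `write_radiance_tiff()` stores an equirectangular radiance image as an
#' uncompressed 32-bit float TIFF holding log10 radiance / 30 (so the
#' natural 0-30 lit range maps into the float payload); masked pixels are
#' stored as zero. `read_radiance_tiff()` inverts the encoding.
#'
#' @param image An [equirect_image()].
#' @param path TIFF path.
#' @return `write_radiance_tiff()` returns `path` invisibly;
#'   `read_radiance_tiff()` returns an [equirect_image()].
#' @export
write_radiance_tiff <- function(image, path) {
  lit <- log10(pmax(image$pixels, .Machine$double.xmin)) / ELF_TIFF_SCALE
  lit[lit < 0] <- 0
  lit[lit > 1] <- 1
  for (k in seq_len(3L)) {
    plane <- lit[, , k]
    plane[!image$mask] <- 0
    lit[, , k] <- plane
  }
  tiff::writeTIFF(lit, path, bits.per.sample = 32L, compression = "none",
                  reduce = FALSE)
  invisible(path)
}

#' @rdname write_radiance_tiff
#' @export
read_radiance_tiff <- function(path) {
  if (!file.exists(path)) abort(paste0("TIFF not found: ", path))
  lit <- tiff::readTIFF(path)
  if (length(dim(lit)) != 3L) abort("Expected a 3-plane radiance TIFF.")
  mask <- lit[, , 1] > 0 | lit[, , 2] > 0 | lit[, , 3] > 0
  px <- 10^(lit * ELF_TIFF_SCALE)
  for (k in seq_len(3L)) {
    plane <- px[, , k]
    plane[!mask] <- NA_real_
    px[, , k] <- plane
  }
  equirect_image(px, mask = mask)
}

# Display tone mapping: per-image normalisation of lit values into [0, 1]
# over a fixed 2.5-lit window below the 99th percentile. Display only;
# never feeds statistics.
tonemap_image <- function(image, window_lit = 2.5, max_size = NULL) {
  px <- image$pixels
  lit <- log10(pmax(px, .Machine$double.xmin))
  top <- quantile(lit[is.finite(lit)], 0.99, names = FALSE)
  out <- (lit - (top - window_lit)) / window_lit
  out[out < 0] <- 0
  out[out > 1] <- 1
  out[is.na(out)] <- 0
  if (!is.null(max_size)) {
    m <- dim(out)[1]
    if (m > max_size) {
      pick <- round(seq(1, m, length.out = max_size))
      out <- out[pick, pick, , drop = FALSE]
    }
  }
  out
}
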