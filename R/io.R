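#' Write a field image as per-channel 16-bit TIFF files
#'
#' One file per channel, named `<plate>_<well>_s<site>_<channel>.tif` with
#' channel in `DAPI`, `YFP`, `TexasRed`.
#'
#' @param field A `momp_field`.
#' @param dir Output directory (created if needed).
#' @param plate Plate identifier used in the filename.
#' @return Invisibly, the written paths (named by channel).
#' @export
write_field_tiff <- function(field, dir, plate = "P01_R1") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(names(field$channels), function(ch) {
    path <- file.path(dir, sprintf("%s_%s_s%d_%s.tif", plate, field$well_id,
                                   field$site_index, ch))
    tiff::writeTIFF(field$channels[[ch]] / 65535, path, bits.per.sample = 16L,
                    compression = "none")
    path
  }, character(1))
  invisible(paths)
}

#' Read a field image from per-channel TIFF files
#'
#' Accepts the filename grammar of [write_field_tiff()], or an explicit named
#' vector of paths (`DAPI`, `YFP`, `TexasRed`).
#'
#' @param dir Directory holding the TIFFs (ignored when `paths` is given).
#' @param plate,well_id,site_index Filename components.
#' @param paths Optional named character vector of the three channel paths.
#' @param pixel_size Micrometers per pixel recorded on the object.
#' @return A `momp_field`.
#' @export
read_field_tiff <- function(dir, plate = "P01_R1", well_id = "B03",
                            site_index = 1L, paths = NULL, pixel_size = 0.65) {
  chans <- c("DAPI", "YFP", "TexasRed")
  if (is.null(paths)) {
    paths <- stats::setNames(file.path(dir, sprintf("%s_%s_s%d_%s.tif", plate,
                                                    well_id, site_index, chans)),
                             chans)
  }
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0) {
    abort(sprintf("missing channel file(s): %s", paste(missing, collapse = ", ")))
  }
  imgs <- lapply(paths[chans], function(p) {
    m <- tiff::readTIFF(p, as.is = TRUE)
    storage.mode(m) <- "integer"
    m
  })
  shp <- lapply(imgs, dim)
  if (length(unique(shp)) != 1) abort("channel images differ in shape.")
  structure(list(channels = imgs, well_id = well_id,
                 site_index = as.integer(site_index), pixel_size = pixel_size),
            class = "momp_field")
}

#' Write ground truth tables for a simulated field
#'
#' Emits `cells.csv` and `puncta.csv` mirroring the detected-output schemas,
#' enabling join-based scoring of detection results against truth.
#'
#' @param truth A `momp_truth`.
#' @param dir Output directory.
#' @param append Append to existing files instead of overwriting.
#' @return Invisibly, the two paths.
#' @export
write_truth_csv <- function(truth, dir, append = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cp <- file.path(dir, "cells.csv"); pp <- file.path(dir, "puncta.csv")
  readr::write_csv(truth$cells, cp, append = append && file.exists(cp))
  pt <- truth$puncta
  pt$well_id <- truth$well_id; pt$site_index <- truth$site_index
  readr::write_csv(pt, pp, append = append && file.exists(pp))
  invisible(c(cells = cp, puncta = pp))
}
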