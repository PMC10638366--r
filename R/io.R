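#' Read a grayscale SEM image from TIFF or PNG
#'
#' SEM rasters rarely carry a calibrated physical scale, so the pixel
#' size must be supplied (from a sidecar config or instrument metadata).
#' RGB input is rejected unless \code{as_gray = TRUE}, in which case the
#' standard luminance conversion is applied.
#'
#' @param path TIFF or PNG file.
#' @param pixel_size micrometers per pixel (required, > 0).
#' @param as_gray convert RGB to luminance instead of failing.
#' @param id specimen id; defaults to the file name.
#' @return a \code{\link{sem_image}}.
#' @export
read_sem_image <- function(path, pixel_size, as_gray = FALSE,
                           id = basename(path)) {
  if (missing(pixel_size) || is.null(pixel_size) || is.na(pixel_size))
    stopf("pixel_size (um/pixel) is required: supply the image calibration")
  if (!file.exists(path)) stopf("file not found: %s", path)
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
               tif = , tiff = tiff::readTIFF(path),
               png = png::readPNG(path),
               stopf("unsupported format '%s' (use TIFF or PNG)", ext))
  bit_depth <- 16L
  if (ext == "png") bit_depth <- 8L
  if (length(dim(px)) == 3L) {
    if (dim(px)[3] == 2L) px <- px[, , 1L]           # gray + alpha
    else if (!as_gray)
      stopf("RGB input: pass as_gray = TRUE for luminance conversion")
    else px <- 0.299 * px[, , 1] + 0.587 * px[, , 2] + 0.114 * px[, , 3]
  }
  sem_image(px, pixel_size, id = id, bit_depth = bit_depth)
}

#' Write an SEM image as 16-bit TIFF or 8-bit PNG
#'
#' @param image a \code{\link{sem_image}}.
#' @param path output path; format from the extension.
#' @return path, invisibly.
#' @export
write_sem_image <- function(image, path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         tif = , tiff = tiff::writeTIFF(image$pixels, path,
                                        bits.per.sample = 16L),
         png = png::writePNG(image$pixels, path),
         stopf("unsupported format '%s'", ext))
  invisible(path)
}

#' Write / read an integer label map as 16-bit TIFF
#'
#' Labels are stored in the 16-bit sample values directly (max 65535
#' labels).
#'
#' @param labelmap a \code{\link{pore_labelmap}} (or chamber label
#'   matrix wrapped in one).
#' @param path .tif path.
#' @return path / a \code{pore_labelmap}.
#' @export
write_labelmap <- function(labelmap, path) {
  lab <- labelmap$labels
  if (max(lab) > 65535L) stopf("too many labels for 16-bit storage")
  tiff::writeTIFF(lab / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_labelmap
#' @param provenance provenance recorded on the read label map.
#' @export
read_labelmap <- function(path, provenance = "classical") {
  lab <- round(tiff::readTIFF(path) * 65535)
  storage.mode(lab) <- "integer"
  pore_labelmap(lab, provenance = provenance)
}

#' Write ground truth as a JSON sidecar
#'
#' Summary ground truth (per-pore and per-chamber tables plus
#' specimen-level parameters); masks are written separately as TIFF.
#'
#' @param truth the \code{truth} element of
#'   \code{\link{generate_specimen}} output.
#' @param path .json path.
#' @return path, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(
    list(pd = truth$pd, mps = truth$mps,
         porosity_pct = truth$porosity_pct,
         test_area_um2 = truth$test_area_um2,
         pores = truth$true_params$pores,
         per_chamber = truth$true_params$per_chamber),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write / read the per-specimen morphometrics table
#'
#' UTF-8 comma-separated CSV with a mandatory header and '.' decimal,
#' matching the per-specimen layout (specimen, location, species, ROI
#' area, pore count, pore density, mean pore size, porosity).
#'
#' @param specimens data.frame of \code{\link{specimen_params}} rows.
#' @param path .csv path.
#' @return path / data.frame.
#' @export
write_specimen_csv <- function(specimens, path) {
  utils::write.csv(specimens, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_specimen_csv
#' @export
read_specimen_csv <- function(path) {
  utils::read.csv(path, fileEncoding = "UTF-8", stringsAsFactors = FALSE)
}
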