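#' Write a B-scan as 16-bit grayscale TIFF
#'
#' Intensities are rounded to integers and stored out of 65535; values above
#' 65535 are clipped with a warning.
#'
#' @param bscan a [BScan-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeBScanTiff <- function(bscan, path) {
  stopifnot(is(bscan, "BScan"))
  m <- round(pixels(bscan))
  if (any(m > 65535)) {
    warning("intensities above 65535 clipped on write")
    m[m > 65535] <- 65535
  }
  tiff::writeTIFF(m / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a 16-bit grayscale TIFF as a B-scan
#'
#' TIFF files carry no OCT metadata, so sampling, fovea position, meridian
#' and eye identity are supplied by the caller (in practice from the run
#' table consumed by [runQuantify()]).
#'
#' @param path TIFF path.
#' @inheritParams BScan
#' @return A [BScan-class] with integer intensities in \[0, 65535\].
#' @export
readBScanTiff <- function(path, axialSpacing, lateralSpacing, foveaCol,
                          meridian = c("vertical", "horizontal"),
                          laterality = c("OD", "OS"), eyeId = "eye") {
  m <- tiff::readTIFF(path)
  if (length(dim(m)) == 3L) m <- m[, , 1L]
  BScan(round(m * 65535), axialSpacing = axialSpacing,
        lateralSpacing = lateralSpacing, foveaCol = foveaCol,
        meridian = match.arg(meridian), laterality = match.arg(laterality),
        eyeId = eyeId)
}

#' Write a 0/1/2 label image as 8-bit PNG
#'
#' Codes: 0 = outside the choroidal band, 1 = stroma, 2 = lumen, stored as
#' raw 8-bit gray levels (0, 1, 2 out of 255).
#'
#' @param labels integer matrix of 0/1/2.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeLabelPng <- function(labels, path) {
  stopifnot(all(labels %in% 0:2))
  png::writePNG(labels / 255, path)
  invisible(path)
}

#' Read a 0/1/2 label PNG
#'
#' @param path PNG path written by [writeLabelPng()] (or following the same
#'   0/1/2 gray-level convention).
#' @return integer matrix of label codes.
#' @export
readLabelPng <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3L) m <- m[, , 1L]
  lab <- round(m * 255)
  storage.mode(lab) <- "integer"
  lab
}
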