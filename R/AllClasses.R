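#' @include AllGenerics.R
NULL

#' B-scan container
#'
#' An SS-OCT B-scan: a 2D grid of non-negative reflectance values with its
#' physical sampling, the foveal center column, the scan meridian and eye
#' identity. Rows index depth (increasing downward), columns index lateral
#' position. All pixel indices in R objects are 1-based; serialized boundary
#' tables and label images use 0-based depths (see [writeBoundaries()]).
#'
#' @slot pixels numeric matrix, rows = depth, columns = lateral position;
#'   non-negative reflectance.
#' @slot axialSpacing micrometers per pixel along depth.
#' @slot lateralSpacing nominal (pre-magnification-correction) micrometers per
#'   pixel along the scan.
#' @slot foveaCol integer column index (1-based) of the foveal center.
#' @slot meridian `"vertical"` or `"horizontal"`.
#' @slot laterality `"OD"` (right eye) or `"OS"` (left eye); decides
#'   nasal/temporal region labels on the horizontal meridian.
#' @slot eyeId opaque eye identifier.
#'
#' @export
setClass("BScan",
  representation(
    pixels = "matrix",
    axialSpacing = "numeric",
    lateralSpacing = "numeric",
    foveaCol = "integer",
    meridian = "character",
    laterality = "character",
    eyeId = "character"
  )
)

setValidity("BScan", function(object) {
  msg <- character()
  if (!is.numeric(object@pixels) || length(dim(object@pixels)) != 2L)
    msg <- c(msg, "'pixels' must be a numeric matrix")
  else if (any(object@pixels < 0, na.rm = TRUE))
    msg <- c(msg, "reflectance values must be non-negative")
  if (length(object@axialSpacing) != 1L || object@axialSpacing <= 0)
    msg <- c(msg, "'axialSpacing' must be a single positive number")
  if (length(object@lateralSpacing) != 1L || object@lateralSpacing <= 0)
    msg <- c(msg, "'lateralSpacing' must be a single positive number")
  if (length(object@foveaCol) != 1L || is.na(object@foveaCol) ||
      object@foveaCol < 1L || object@foveaCol > ncol(object@pixels))
    msg <- c(msg, "'foveaCol' must lie within the image width")
  if (!object@meridian %in% c("vertical", "horizontal"))
    msg <- c(msg, "'meridian' must be \"vertical\" or \"horizontal\"")
  if (!object@laterality %in% c("OD", "OS"))
    msg <- c(msg, "'laterality' must be \"OD\" or \"OS\"")
  if (length(msg)) msg else TRUE
})

#' Construct a BScan
#'
#' @param pixels numeric matrix of reflectance (rows = depth).
#' @param axialSpacing,lateralSpacing micrometers per pixel.
#' @param foveaCol 1-based foveal center column.
#' @param meridian `"vertical"` or `"horizontal"`.
#' @param laterality `"OD"` or `"OS"`.
#' @param eyeId identifier string.
#' @return A [BScan-class] object.
#' @examples
#' b <- BScan(matrix(runif(200), 20, 10), axialSpacing = 3, lateralSpacing = 12,
#'            foveaCol = 5, meridian = "vertical")
#' dim(pixels(b))
#' @export
BScan <- function(pixels, axialSpacing, lateralSpacing, foveaCol,
                  meridian = c("vertical", "horizontal"),
                  laterality = c("OD", "OS"), eyeId = "eye") {
  meridian <- match.arg(meridian)
  laterality <- match.arg(laterality)
  new("BScan", pixels = pixels, axialSpacing = as.numeric(axialSpacing),
      lateralSpacing = as.numeric(lateralSpacing),
      foveaCol = as.integer(foveaCol), meridian = meridian,
      laterality = laterality, eyeId = as.character(eyeId))
}

#' Choroid boundary pair
#'
#' Per-column depths of the inner choroid boundary (`upperPx`) and the
#' choroid-sclera interface (`lowerPx`), 1-based and inclusive: `upperPx` is
#' the first image row belonging to the choroidal band and `lowerPx` the last,
#' so band thickness in pixels is `lowerPx - upperPx + 1`. Columns where either
#' interface is undefined (or where lower < upper was detected) carry `NA` and
#' `validCols = FALSE`; such columns are excluded from all downstream sums.
#'
#' @slot upperPx integer vector, one entry per image column (NA if invalid).
#' @slot lowerPx integer vector, same length (NA if invalid).
#' @slot validCols logical vector marking columns with a usable boundary pair.
#'
#' @export
setClass("ChoroidBoundaries",
  representation(
    upperPx = "integer",
    lowerPx = "integer",
    validCols = "logical"
  )
)

setValidity("ChoroidBoundaries", function(object) {
  msg <- character()
  n <- length(object@upperPx)
  if (length(object@lowerPx) != n || length(object@validCols) != n)
    msg <- c(msg, "'upperPx', 'lowerPx' and 'validCols' must have equal length")
  v <- object@validCols
  if (any(v & (is.na(object@upperPx) | is.na(object@lowerPx))))
    msg <- c(msg, "valid columns must have non-NA boundaries")
  ok <- v & !is.na(object@upperPx) & !is.na(object@lowerPx)
  if (any(object@lowerPx[ok] < object@upperPx[ok]))
    msg <- c(msg, "lowerPx < upperPx on a column marked valid")
  if (any(object@upperPx[ok] < 1L))
    msg <- c(msg, "boundary depths must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Construct ChoroidBoundaries
#'
#' Columns where `lower < upper` are flagged invalid with a warning, never
#' silently reordered.
#'
#' @param upperPx,lowerPx per-column 1-based depths (NA allowed).
#' @param validCols optional logical; defaults to both depths being non-NA.
#' @return A [ChoroidBoundaries-class] object.
#' @export
ChoroidBoundaries <- function(upperPx, lowerPx, validCols = NULL) {
  upperPx <- as.integer(round(upperPx))
  lowerPx <- as.integer(round(lowerPx))
  if (is.null(validCols)) validCols <- !is.na(upperPx) & !is.na(lowerPx)
  bad <- validCols & !is.na(upperPx) & !is.na(lowerPx) & (lowerPx < upperPx)
  if (any(bad)) {
    warning(sum(bad), " column(s) with lower < upper flagged invalid")
    validCols[bad] <- FALSE
  }
  upperPx[!validCols] <- NA_integer_
  lowerPx[!validCols] <- NA_integer_
  new("ChoroidBoundaries", upperPx = upperPx, lowerPx = lowerPx,
      validCols = validCols)
}

#' Binarized choroid band
#'
#' Per-pixel lumen/stroma classification restricted to the choroidal band.
#' Label codes: 0 = outside the band (or invalid column), 1 = stroma,
#' 2 = lumen. Counts cover valid columns only and always partition the band:
#' `lumenPx + stromaPx` equals the number of band pixels on valid columns.
#'
#' @slot labels integer matrix of 0/1/2 codes, same shape as the image.
#' @slot lumenPx,stromaPx integer pixel counts over valid columns.
#' @slot validCols logical per-column validity inherited from the boundaries.
#' @slot config list echoing the binarization configuration used.
#'
#' @export
setClass("BinarizedChoroid",
  representation(
    labels = "matrix",
    lumenPx = "integer",
    stromaPx = "integer",
    validCols = "logical",
    config = "list"
  )
)

setValidity("BinarizedChoroid", function(object) {
  msg <- character()
  if (!all(object@labels %in% 0:2))
    msg <- c(msg, "labels must be 0 (outside), 1 (stroma) or 2 (lumen)")
  if (sum(object@labels == 2L) != object@lumenPx)
    msg <- c(msg, "lumenPx does not match the label tally")
  if (sum(object@labels == 1L) != object@stromaPx)
    msg <- c(msg, "stromaPx does not match the label tally")
  if (length(msg)) msg else TRUE
})

setMethod("show", "BScan", function(object) {
  cat("BScan <", object@eyeId, "> ", nrow(object@pixels), " x ",
      ncol(object@pixels), " px, ", object@meridian, " meridian (",
      object@laterality, ")\n", sep = "")
  cat("  spacing: ", object@axialSpacing, " um/px axial, ",
      object@lateralSpacing, " um/px lateral (nominal); fovea at column ",
      object@foveaCol, "\n", sep = "")
})

setMethod("show", "ChoroidBoundaries", function(object) {
  nv <- sum(object@validCols)
  cat("ChoroidBoundaries: ", length(object@upperPx), " columns, ",
      nv, " valid\n", sep = "")
  if (nv) {
    t <- bandThicknessPx(object)
    cat("  band thickness (px): median ", stats::median(t, na.rm = TRUE),
        ", range [", min(t, na.rm = TRUE), ", ", max(t, na.rm = TRUE),
        "]\n", sep = "")
  }
})

setMethod("show", "BinarizedChoroid", function(object) {
  tot <- object@lumenPx + object@stromaPx
  cat("BinarizedChoroid: ", object@lumenPx, " lumen / ", object@stromaPx,
      " stroma px", sep = "")
  if (tot > 0) cat(" (lumen fraction ", round(object@lumenPx / tot, 3), ")",
                   sep = "")
  cat("\n  window ", object@config$window_px, " px, k = ", object@config$k,
      "\n", sep = "")
})

#' @describeIn BScan-class reflectance matrix
#' @param x object
#' @export
setMethod("pixels", "BScan", function(x) x@pixels)

#' @describeIn BScan-class axial sampling, micrometers per pixel
#' @export
setMethod("axialSpacing", "BScan", function(x) x@axialSpacing)

#' @describeIn BScan-class nominal lateral sampling, micrometers per pixel
#' @export
setMethod("lateralSpacing", "BScan", function(x) x@lateralSpacing)

#' @describeIn BScan-class 1-based foveal center column
#' @export
setMethod("foveaCol", "BScan", function(x) x@foveaCol)

#' @describeIn BScan-class scan meridian
#' @export
setMethod("meridian", "BScan", function(x) x@meridian)

#' @describeIn BScan-class eye laterality
#' @export
setMethod("laterality", "BScan", function(x) x@laterality)

#' @describeIn BScan-class eye identifier
#' @export
setMethod("eyeId", "BScan", function(x) x@eyeId)

#' @describeIn ChoroidBoundaries-class inner boundary depths (1-based)
#' @param x object
#' @export
setMethod("upperPx", "ChoroidBoundaries", function(x) x@upperPx)

#' @describeIn ChoroidBoundaries-class choroid-sclera interface depths
#' @export
setMethod("lowerPx", "ChoroidBoundaries", function(x) x@lowerPx)

#' @describeIn ChoroidBoundaries-class per-column validity
#' @export
setMethod("validCols", "ChoroidBoundaries", function(x) x@validCols)

#' @describeIn ChoroidBoundaries-class per-column band thickness in pixels
#'   (inclusive convention, `lower - upper + 1`; NA on invalid columns)
#' @export
setMethod("bandThicknessPx", "ChoroidBoundaries",
          function(x) x@lowerPx - x@upperPx + 1L)

#' @describeIn BinarizedChoroid-class 0/1/2 label matrix
#' @param x object
#' @export
setMethod("choroidLabels", "BinarizedChoroid", function(x) x@labels)

#' @describeIn BinarizedChoroid-class lumen pixel count (valid columns)
#' @export
setMethod("lumenPixels", "BinarizedChoroid", function(x) x@lumenPx)

#' @describeIn BinarizedChoroid-class stroma pixel count (valid columns)
#' @export
setMethod("stromaPixels", "BinarizedChoroid", function(x) x@stromaPx)

#' @describeIn BinarizedChoroid-class per-column validity
#' @export
setMethod("validCols", "BinarizedChoroid", function(x) x@validCols)
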