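#' Read choroid boundaries from a label image or per-column table
#'
#' Accepts either a label matrix / label-PNG path using the 0 = outside,
#' 1 = stroma, 2 = lumen convention (the band is any non-zero label; the
#' boundary pair per column is the first and last non-zero row), or a
#' per-column boundary table / CSV with columns `col`, `upper_px`,
#' `lower_px`, `valid` where depths are 0-based (the serialization
#' convention; in-memory objects are 1-based). Columns where lower < upper
#' are flagged invalid with a warning, never silently reordered.
#'
#' @param source a matrix of labels, a data.frame boundary table, or a file
#'   path ending in `.png` (label image) or `.csv` (boundary table).
#' @return A [ChoroidBoundaries-class].
#' @seealso [writeBoundaries()] for the inverse of the CSV form.
#' @export
readBoundaries <- function(source) {
  if (is.character(source)) {
    if (!file.exists(source)) stop("cannot read '", source, "'")
    source <- if (grepl("\\.png$", source, ignore.case = TRUE))
      readLabelPng(source)
    else utils::read.csv(source)
  }
  if (is.matrix(source)) {
    b <- .boundariesFromLabels(source)
  } else if (is.data.frame(source)) {
    need <- c("col", "upper_px", "lower_px", "valid")
    if (!all(need %in% names(source)))
      stop("boundary table must have columns ", paste(need, collapse = ", "))
    source <- source[order(source$col), ]
    up <- ifelse(source$valid, source$upper_px + 1L, NA_integer_)
    lo <- ifelse(source$valid, source$lower_px + 1L, NA_integer_)
    b <- ChoroidBoundaries(up, lo)
  } else stop("unsupported boundary source")
  if (!any(validCols(b)))
    stop("no valid boundary columns in source")
  b
}

.boundariesFromLabels <- function(labels) {
  w <- ncol(labels)
  up <- rep(NA_integer_, w); lo <- rep(NA_integer_, w)
  for (j in seq_len(w)) {
    rows <- which(labels[, j] != 0)
    if (length(rows)) { up[j] <- rows[1L]; lo[j] <- rows[length(rows)] }
  }
  ChoroidBoundaries(up, lo)
}

#' Write choroid boundaries to CSV
#'
#' Serializes to the interchange convention: 0-based `col`, 0-based
#' `upper_px`/`lower_px` depths (empty for invalid columns) and a `valid`
#' flag. [readBoundaries()] on the result reproduces the object exactly.
#'
#' @param boundaries a [ChoroidBoundaries-class].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeBoundaries <- function(boundaries, path) {
  stopifnot(is(boundaries, "ChoroidBoundaries"))
  df <- data.frame(col = seq_along(upperPx(boundaries)) - 1L,
                   upper_px = upperPx(boundaries) - 1L,
                   lower_px = lowerPx(boundaries) - 1L,
                   valid = validCols(boundaries))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Baseline choroid boundary finder
#'
#' A deterministic edge-based stand-in segmenter: per column, the upper
#' boundary is placed at the outermost strong positive axial intensity step
#' (the background-to-band edge; an interior lumen-to-stroma edge may be
#' stronger but is never the first) and the lower boundary at the last
#' strong negative step below it, then both are median-smoothed laterally.
#' It is intended for synthetic or high-contrast images so that end-to-end
#' runs need no externally supplied segmentation; the pipeline's primary
#' path consumes supplied (checked/corrected) boundary masks.
#'
#' Columns whose strongest step is weaker than `min_step_frac` times the
#' image dynamic range are marked invalid; if no column has a usable edge
#' (e.g., a uniform image) an error is raised.
#'
#' @param image a [BScan-class].
#' @param smoothing odd lateral median window in pixels.
#' @param min_step_frac minimum step size as a fraction of the image dynamic
#'   range for a column to count as segmented.
#' @return A [ChoroidBoundaries-class].
#' @export
baselineSegment <- function(image, smoothing = 15L, min_step_frac = 0.1) {
  stopifnot(is(image, "BScan"))
  m <- pixels(image)
  rng <- max(m) - min(m)
  if (rng <= 0) stop("no boundary-like edges found: image is uniform")
  w <- ncol(m)
  up <- rep(NA_real_, w); lo <- rep(NA_real_, w)
  floorStep <- min_step_frac * rng
  for (j in seq_len(w)) {
    d <- diff(m[, j])
    rises <- which(d >= floorStep)
    if (!length(rises)) next
    iUp <- rises[1L]
    drops <- which(d <= -floorStep)
    drops <- drops[drops > iUp]
    if (!length(drops)) next
    up[j] <- iUp + 1L              # first band row (after the rise)
    lo[j] <- drops[length(drops)]  # last band row (before the final drop)
  }
  ok <- !is.na(up)
  if (!any(ok)) stop("no boundary-like edges found in any column")
  if (sum(ok) > smoothing) {
    sm <- as.integer(smoothing)
    if (sm %% 2L == 0L) sm <- sm + 1L
    up[ok] <- round(stats::runmed(up[ok], sm))
    lo[ok] <- round(stats::runmed(lo[ok], sm))
  }
  ChoroidBoundaries(up, lo)
}

#' Score boundaries against a reference
#'
#' Mean and per-column absolute depth error on columns valid in both, for
#' validating a segmentation against ground truth.
#'
#' @param est,ref [ChoroidBoundaries-class] objects of equal width.
#' @return list with `mean_abs_error_px`, per-column errors, and the shared
#'   valid-column count.
#' @export
boundaryError <- function(est, ref) {
  both <- validCols(est) & validCols(ref)
  eu <- abs(upperPx(est) - upperPx(ref))[both]
  el <- abs(lowerPx(est) - lowerPx(ref))[both]
  list(mean_abs_error_px = mean(c(eu, el)),
       upper_abs_err = eu, lower_abs_err = el, n_cols = sum(both))
}
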