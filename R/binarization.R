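#' Binarization configuration
#'
#' Settings for the Niblack auto-local threshold used to classify choroidal
#' pixels into vascular lumen (dark) and extravascular stroma (bright). The
#' per-pixel threshold is T = mu_w + k * sigma_w, with mu_w and sigma_w the
#' mean and population standard deviation over a square window centered on
#' the pixel; a pixel is lumen iff its value is strictly below T (ties go to
#' stroma; this rule is fixed). Window statistics are computed on the full
#' image (band-external pixels contribute to windows) with reflective edge
#' padding.
#'
#' Typical CVI work uses a window comparable to the choroidal band thickness
#' and a small negative k to suppress speckle-driven false lumens; the
#' defaults are window 51 px and k = -0.2 and are echoed in every output.
#'
#' @param window_px odd integer side length of the square window, >= 3.
#' @param k Niblack coefficient (real, typically negative).
#' @param median_prefilter apply a 3x3 median despeckle before thresholding
#'   (off by default; recorded in the config when on).
#' @return list of class `"BinarizationConfig"`.
#' @export
binarizationConfig <- function(window_px = 51L, k = -0.2,
                               median_prefilter = FALSE) {
  window_px <- as.integer(window_px)
  if (is.na(window_px) || window_px < 3L || window_px %% 2L == 0L)
    stop("'window_px' must be an odd integer >= 3")
  if (!is.numeric(k) || length(k) != 1L || is.na(k))
    stop("'k' must be a single real number")
  structure(list(window_px = window_px, k = k,
                 median_prefilter = isTRUE(median_prefilter),
                 tie_rule = "value < threshold => lumen"),
            class = "BinarizationConfig")
}

# symmetric (edge-inclusive) reflective padding of a matrix by r on all sides
.padReflect <- function(m, r) {
  n <- nrow(m); p <- ncol(m)
  ri <- c(pmin(r:1, n), 1:n, pmax(n - (1:r) + 1L, 1L))
  ci <- c(pmin(r:1, p), 1:p, pmax(p - (1:r) + 1L, 1L))
  m[ri, ci, drop = FALSE]
}

# windowed sums via a summed-area table with a zero border
.windowSums <- function(padded, w, nOut, pOut) {
  S <- matrix(0, nrow(padded) + 1L, ncol(padded) + 1L)
  S[-1L, -1L] <- apply(apply(padded, 2L, cumsum), 1L, cumsum) |> t()
  i1 <- seq_len(nOut); j1 <- seq_len(pOut)
  S[i1 + w, j1 + w, drop = FALSE] - S[i1, j1 + w, drop = FALSE] -
    S[i1 + w, j1, drop = FALSE] + S[i1, j1, drop = FALSE]
}

#' Per-pixel Niblack threshold surface
#'
#' Computes T = mu_w + k * sigma_w for every pixel of a matrix, with
#' population-SD window statistics and symmetric reflective edge padding.
#'
#' @param m numeric matrix.
#' @param window_px odd window side length.
#' @param k Niblack coefficient.
#' @return numeric matrix of thresholds, same shape as `m`.
#' @export
niblackThreshold <- function(m, window_px = 51L, k = -0.2) {
  w <- as.integer(window_px)
  stopifnot(w >= 3L, w %% 2L == 1L)
  r <- (w - 1L) %/% 2L
  pad <- .padReflect(m, r)
  n <- w * w
  s1 <- .windowSums(pad, w, nrow(m), ncol(m))
  s2 <- .windowSums(pad * pad, w, nrow(m), ncol(m))
  mu <- s1 / n
  va <- pmax(s2 / n - mu * mu, 0)
  mu + k * sqrt(va)
}

# 3x3 median filter with reflective padding (optional despeckle)
.median3 <- function(m) {
  pad <- .padReflect(m, 1L)
  out <- m
  for (i in seq_len(nrow(m)))
    for (j in seq_len(ncol(m)))
      out[i, j] <- stats::median(pad[i:(i + 2L), j:(j + 2L)])
  out
}

#' Niblack binarization of the choroidal band
#'
#' Classifies every pixel inside the segmented choroidal band as lumen or
#' stroma with the Niblack auto-local threshold (see [binarizationConfig()]).
#' Thresholds are computed on the raw full image, then the band is overlaid:
#' masking the windows to the band would bias thresholds near the boundaries.
#' Columns marked invalid in the boundaries contribute no band pixels. The
#' labels under any positive affine intensity rescaling v' = a*v + b (a > 0)
#' are identical, because the threshold surface transforms the same way.
#'
#' @param image a [BScan-class].
#' @param boundaries a [ChoroidBoundaries-class] for the same image.
#' @param config a [binarizationConfig()].
#' @return A [BinarizedChoroid-class]; `lumenPixels() + stromaPixels()` always
#'   equals the number of band pixels on valid columns.
#' @export
niblackBinarize <- function(image, boundaries, config = binarizationConfig()) {
  stopifnot(is(image, "BScan"), is(boundaries, "ChoroidBoundaries"))
  m <- pixels(image)
  if (length(upperPx(boundaries)) != ncol(m))
    stop("boundaries cover ", length(upperPx(boundaries)),
         " columns but the image has ", ncol(m))
  v <- validCols(boundaries)
  up <- upperPx(boundaries); lo <- lowerPx(boundaries)
  if (!any(v)) stop("empty choroidal band: no valid boundary columns")
  if (any(lo[v] > nrow(m)))
    stop("boundaries exceed the image height")
  src <- if (isTRUE(config$median_prefilter)) .median3(m) else m
  thr <- niblackThreshold(src, config$window_px, config$k)
  labels <- matrix(0L, nrow(m), ncol(m))
  for (j in which(v)) {
    rows <- up[j]:lo[j]
    labels[rows, j] <- ifelse(src[rows, j] < thr[rows, j], 2L, 1L)
  }
  new("BinarizedChoroid", labels = labels,
      lumenPx = sum(labels == 2L), stromaPx = sum(labels == 1L),
      validCols = v, config = unclass(config))
}
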