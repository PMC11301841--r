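#' Configuration for synthetic B-scan generation
#'
#' Describes a synthetic SS-OCT B-scan with a choroid-like band between two
#' smooth wavy boundaries, elliptical low-reflectance vessel lumens placed to
#' hit a target lumen-pixel fraction, and multiplicative gamma speckle. The
#' generator emulates the appearance a CVI pipeline consumes: dark lumens
#' against brighter extravascular stroma inside a segmented band, over a dark
#' background. It provides exact, noise-free ground truth (boundaries, lumen
#' mask, achieved lumen fraction), so downstream binarization and metric code
#' can be validated against a known answer.
#'
#' Defaults describe a 6-mm macular cross-section sampled at 12 um/px
#' laterally and 3 um/px axially with a 270-um-thick choroid, in the range
#' typical of highly myopic adults. Scanner intensity statistics are not
#' calibrated to any device: `speckle_shape` (gamma shape of unit-mean
#' multiplicative noise; larger = milder speckle, `Inf` = noise-free) and the
#' class reflectance means are free, documented knobs. The default shape of
#' 80 (coefficient of variation about 0.11) emulates the multi-frame-averaged
#' line scans a CVI pipeline consumes, where registration averaging has
#' suppressed the raw fully developed speckle (CV about 0.52); single-frame
#' speckle can be emulated with shapes near 4-8.
#'
#' @param height_px,width_px image size in pixels.
#' @param axial_um_per_px,lateral_um_per_px sampling, micrometers per pixel
#'   (lateral is nominal, pre-magnification-correction).
#' @param choroid_mean_thickness_um mean band thickness, micrometers.
#' @param boundary_waviness dimensionless amplitude of the low-frequency
#'   boundary perturbation, as a fraction of mean band thickness.
#' @param target_lumen_fraction desired lumen-pixel share of the band, in
#'   \[0, 1\]; the generator stops within +/- 0.02 of it.
#' @param lumen_reflectance_mean,stroma_reflectance_mean class intensity
#'   means; lumen must be darker than stroma.
#' @param background_reflectance intensity outside the band. The default
#'   (40) sits just below the lumen level, emulating that the choroid
#'   borders tissue of low-to-moderate reflectance (outer retina above,
#'   sclera shadow below) rather than void; a near-lumen background keeps
#'   local thresholds in band-edge windows between the lumen and stroma
#'   levels, as in real scans.
#' @param speckle_shape gamma shape of the multiplicative speckle (> 0, or
#'   `Inf` for noise-free images).
#' @param lumen_semiaxes_px ranges for the lumen ellipse semi-axes, a list
#'   with `lateral = c(min, max)` and `axial = c(min, max)` in pixels
#'   (vessels are wider than tall).
#' @param seed integer seed; identical config + seed gives bit-identical
#'   output.
#' @return list of class `"ImageSimConfig"`.
#' @export
imageSimConfig <- function(height_px = 256L, width_px = 512L,
                           axial_um_per_px = 3, lateral_um_per_px = 12,
                           choroid_mean_thickness_um = 270,
                           boundary_waviness = 0.08,
                           target_lumen_fraction = 0.4,
                           lumen_reflectance_mean = 55,
                           stroma_reflectance_mean = 155,
                           background_reflectance = 40,
                           speckle_shape = 80,
                           lumen_semiaxes_px = list(lateral = c(4, 14),
                                                    axial = c(2, 8)),
                           seed = 1L) {
  cfg <- list(height_px = as.integer(height_px),
              width_px = as.integer(width_px),
              axial_um_per_px = axial_um_per_px,
              lateral_um_per_px = lateral_um_per_px,
              choroid_mean_thickness_um = choroid_mean_thickness_um,
              boundary_waviness = boundary_waviness,
              target_lumen_fraction = target_lumen_fraction,
              lumen_reflectance_mean = lumen_reflectance_mean,
              stroma_reflectance_mean = stroma_reflectance_mean,
              background_reflectance = background_reflectance,
              speckle_shape = speckle_shape,
              lumen_semiaxes_px = lumen_semiaxes_px,
              seed = as.integer(seed))
  if (cfg$target_lumen_fraction < 0 || cfg$target_lumen_fraction > 1)
    stop("'target_lumen_fraction' must lie in [0, 1]")
  if (cfg$lumen_reflectance_mean >= cfg$stroma_reflectance_mean)
    stop("lumen reflectance must be below stroma reflectance")
  if (cfg$axial_um_per_px <= 0 || cfg$lateral_um_per_px <= 0)
    stop("pixel spacings must be positive")
  if (cfg$speckle_shape <= 0)
    stop("'speckle_shape' must be positive (use Inf for noise-free)")
  if (cfg$boundary_waviness < 0) stop("'boundary_waviness' must be >= 0")
  structure(cfg, class = "ImageSimConfig")
}

# evaluate a sum of 2-4 low-frequency sinusoids across image columns
.wavyProfile <- function(width, amplitude) {
  nsin <- sample(2:4, 1L)
  x <- seq_len(width) / width
  y <- numeric(width)
  for (i in seq_len(nsin)) {
    freq <- stats::runif(1L, 0.5, 2)
    phase <- stats::runif(1L, 0, 2 * pi)
    y <- y + sin(2 * pi * freq * x + phase)
  }
  amplitude * y / nsin
}

#' Simulate a B-scan with known choroid geometry and lumen fraction
#'
#' Builds the band between two smooth boundaries, then adds elliptical
#' lumens (clipped to the band; overlapping ellipses merge) one at a time
#' until the lumen-pixel fraction of the band is within +/- 0.02 of
#' `target_lumen_fraction`, then applies multiplicative gamma speckle to the
#' whole image. The returned truth is noise-free and exact:
#' `true_lumen_fraction` is the lumen-pixel count divided by the band-pixel
#' count. For a fixed seed, raising the target only appends ellipses, so the
#' achieved fraction is non-decreasing in the target.
#'
#' @param config an [imageSimConfig()].
#' @param meridian,laterality,eyeId metadata for the returned [BScan-class].
#' @return list with elements `bscan` (a [BScan-class]), and `truth`: a list
#'   with `boundaries` ([ChoroidBoundaries-class]), `lumen_mask` (logical
#'   matrix), `band_mask` (logical matrix), `true_lumen_fraction`,
#'   `target_lumen_fraction` and `tolerance` (0.02).
#' @examples
#' sim <- simulateBScan(imageSimConfig(target_lumen_fraction = 0.3, seed = 7))
#' sim$truth$true_lumen_fraction
#' @export
simulateBScan <- function(config = imageSimConfig(),
                          meridian = c("vertical", "horizontal"),
                          laterality = c("OD", "OS"), eyeId = "sim-eye") {
  stopifnot(inherits(config, "ImageSimConfig"))
  meridian <- match.arg(meridian)
  laterality <- match.arg(laterality)
  oldseed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(oldseed))
    assign(".Random.seed", oldseed, envir = globalenv()))
  set.seed(config$seed)

  h <- config$height_px; w <- config$width_px
  tpx <- config$choroid_mean_thickness_um / config$axial_um_per_px
  amp <- config$boundary_waviness * tpx
  upper <- round(0.35 * h + .wavyProfile(w, amp))
  thick <- round(tpx * (1 + .wavyProfile(w, config$boundary_waviness)))
  lower <- upper + pmax(thick, 2L) - 1L
  if (any(upper < 2L) || any(lower > h - 1L))
    stop("choroid band does not fit the image; reduce thickness or waviness")
  boundaries <- ChoroidBoundaries(upper, lower)

  bandMask <- matrix(FALSE, h, w)
  for (j in seq_len(w)) bandMask[upper[j]:lower[j], j] <- TRUE
  nBand <- sum(bandMask)

  lumenMask <- matrix(FALSE, h, w)
  target <- config$target_lumen_fraction
  tol <- 0.02
  if (target > 0) {
    axL <- config$lumen_semiaxes_px$lateral
    axA <- config$lumen_semiaxes_px$axial
    frac <- 0
    it <- 0L
    maxIt <- 50000L
    while (frac < target - 0.005 && it < maxIt) {
      it <- it + 1L
      c0 <- stats::runif(1L, 1, w)
      j0 <- max(1L, min(w, round(c0)))
      r0 <- stats::runif(1L, upper[j0], lower[j0])
      a <- stats::runif(1L, axL[1], axL[2])
      b <- stats::runif(1L, axA[1], axA[2])
      jj <- max(1L, floor(c0 - a)):min(w, ceiling(c0 + a))
      ii <- max(1L, floor(r0 - b)):min(h, ceiling(r0 + b))
      el <- outer(((ii - r0) / b)^2, ((jj - c0) / a)^2, `+`) <= 1
      sub <- lumenMask[ii, jj, drop = FALSE]
      sub[el & bandMask[ii, jj, drop = FALSE]] <- TRUE
      lumenMask[ii, jj] <- sub
      frac <- sum(lumenMask) / nBand
    }
    if (abs(frac - target) > tol)
      stop("target lumen fraction ", target, " unreachable; achieved ",
           signif(frac, 4), " after ", it, " ellipses")
  }
  trueFrac <- sum(lumenMask) / nBand

  img <- matrix(config$background_reflectance, h, w)
  img[bandMask] <- config$stroma_reflectance_mean
  img[lumenMask] <- config$lumen_reflectance_mean
  if (is.finite(config$speckle_shape)) {
    sp <- config$speckle_shape
    img <- img * matrix(stats::rgamma(h * w, shape = sp, rate = sp), h, w)
  }

  bscan <- BScan(img, axialSpacing = config$axial_um_per_px,
                 lateralSpacing = config$lateral_um_per_px,
                 foveaCol = as.integer(round(w / 2)),
                 meridian = meridian, laterality = laterality, eyeId = eyeId)
  list(bscan = bscan,
       truth = list(boundaries = boundaries, lumen_mask = lumenMask,
                    band_mask = bandMask, true_lumen_fraction = trueFrac,
                    target_lumen_fraction = target, tolerance = tol))
}
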