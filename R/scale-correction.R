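#' Bennett lateral magnification factor
#'
#' Ocular magnification scales the lateral extent of an OCT scan with axial
#' length. Following Bennett's formula t = p * q * s with the eye factor
#' q = 0.01306 * (AL - 1.82) and the device factor p fixed so that an eye of
#' axial length 24.4 mm images at unit magnification, the true-to-nominal
#' scan-length ratio is
#'
#'   factor = t / s = (AL - 1.82) / 22.58
#'
#' Lateral pixel spacings and lateral distances are multiplied by this factor;
#' axial distances are left uncorrected (axial OCT sampling is optical-path
#' based).
#'
#' @param AL axial length in millimeters; must lie in the physiological range
#'   \[15, 40\] mm (values outside produce an error, preventing nonsensical
#'   near-zero or negative factors).
#' @return Dimensionless scale factor t/s. Exactly 1 at AL = 24.4 mm.
#' @examples
#' lateralFactor(24.4)   # 1: true length equals nominal
#' lateralFactor(28)     # elongated eye, image shows more than nominal 6 mm
#' @export
lateralFactor <- function(AL) {
  if (!is.numeric(AL) || anyNA(AL))
    stop("'AL' must be numeric and non-missing")
  if (any(AL < 15 | AL > 40))
    stop("axial length ", paste(AL[AL < 15 | AL > 40], collapse = ", "),
         " mm outside the physiological range [15, 40] mm")
  (AL - 1.82) / 22.58
}

# device magnification factor p implied by unit magnification at AL 24.4 mm
.BENNETT_P <- 1 / (0.01306 * 22.58)

#' Eye magnification factor q
#'
#' The eye-dependent component of Bennett's correction,
#' q = 0.01306 * (AL - 1.82). The product p * q with the implied device
#' constant p equals [lateralFactor()].
#'
#' @inheritParams lateralFactor
#' @return Dimensionless q.
#' @export
eyeMagnification <- function(AL) {
  if (any(AL < 15 | AL > 40)) stop("axial length outside [15, 40] mm")
  0.01306 * (AL - 1.82)
}

#' Convert pixel-unit choroidal metrics to physical units
#'
#' Applies the axial-length magnification correction to pixel measurements:
#' lateral distances are scaled by `factor * lateralSpacing`, axial distances
#' by `axialSpacing` alone, and areas by `factor * lateralSpacing *
#' axialSpacing`. Thickness is returned in micrometers and areas in square
#' millimeters. The luminal/stromal area ratio (CVI) is invariant under the
#' correction because numerator and denominator scale identically.
#'
#' @param thicknessPx axial extents in pixels (may be a vector).
#' @param areaPx pixel counts (may be a vector).
#' @param axialSpacing,lateralSpacing micrometers per pixel.
#' @param AL axial length in mm.
#' @return list with `thickness_um`, `area_mm2` and the `factor` used.
#' @examples
#' applyCorrection(thicknessPx = 100, areaPx = 5000,
#'                 axialSpacing = 2, lateralSpacing = 12, AL = 24.4)
#' @export
applyCorrection <- function(thicknessPx = numeric(), areaPx = numeric(),
                            axialSpacing, lateralSpacing, AL) {
  stopifnot(axialSpacing > 0, lateralSpacing > 0)
  f <- lateralFactor(AL)
  list(
    thickness_um = thicknessPx * axialSpacing,
    area_mm2 = areaPx * f * lateralSpacing * axialSpacing * 1e-6,
    factor = f
  )
}
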