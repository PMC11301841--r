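#' Fovea-centered region grid for a 6-mm section
#'
#' Partitions the analyzed 6-mm cross-section into five half-open intervals
#' of signed true distance from the fovea (millimeters, after magnification
#' correction): the 1-mm fovea C \[-0.5, 0.5), the 1-mm parafovea on either
#' side \[0.5, 1.5), and the 1.5-mm perifovea \[1.5, 3.0). Intervals tile
#' \[-3, 3) without overlap. Region names follow the meridian: superior (S)
#' / inferior (I) on the vertical scan and nasal (N) / temporal (T) on the
#' horizontal scan, where the negative (lower-column) side is nasal for a
#' right eye (OD) and temporal for a left eye (OS), so OD and OS mirror.
#' Perifoveal regions carry `normalize = 1.5`: their luminal/stromal areas
#' are divided by 1.5 when width-normalized values are requested, removing
#' the effect of the wider interval.
#'
#' @param meridian `"vertical"` or `"horizontal"`.
#' @param laterality `"OD"` or `"OS"` (used on the horizontal meridian only).
#' @return data.frame with columns `name`, `a_mm`, `b_mm` (half-open
#'   interval), `width_mm`, `normalize`.
#' @examples
#' partitionRegions("horizontal", "OD")
#' @export
partitionRegions <- function(meridian = c("vertical", "horizontal"),
                             laterality = c("OD", "OS")) {
  meridian <- match.arg(meridian)
  laterality <- match.arg(laterality)
  a <- c(-3, -1.5, -0.5, 0.5, 1.5)
  b <- c(-1.5, -0.5, 0.5, 1.5, 3)
  names <- if (meridian == "vertical") c("I2", "I1", "C", "S1", "S2")
  else if (laterality == "OD") c("N2", "N1", "C", "T1", "T2")
  else c("T2", "T1", "C", "N1", "N2")
  data.frame(name = names, a_mm = a, b_mm = b, width_mm = b - a,
             normalize = ifelse(b - a > 1, 1.5, 1))
}

#' Regional and meridian choroidal metrics
#'
#' Computes choroidal thickness (ChT), luminal area (LA), stromal area (SA),
#' total choroidal area (TCA = LA + SA) and the choroidal vascularity index
#' (CVI = LA / TCA) per region and for the whole 6-mm section of one
#' meridian, in physical units after the Bennett magnification correction
#' (see [lateralFactor()]).
#'
#' A column belongs to the region whose half-open interval contains its
#' center's corrected signed distance from the fovea; columns invalid in the
#' boundaries are excluded everywhere and the contributing share is reported
#' as `valid_fraction`. Per region, ChT is the mean per-column band thickness
#' (inclusive convention, `lower - upper + 1` px, times the axial spacing);
#' LA and SA are lumen/stroma pixel counts times the corrected pixel area.
#' Meridian LA/SA are totals over the section (the region values sum to them
#' exactly) and meridian ChT is the mean thickness, so LA + SA approximates
#' mean ChT (mm) x 6 mm. Regions with no valid column get `NA` metrics
#' (missing, not zero). If the image does not extend 3 true millimeters from
#' the fovea on either side the truncated share of each region is reported
#' in `clamped_fraction` and a warning is raised.
#'
#' @param image a [BScan-class].
#' @param boundaries a [ChoroidBoundaries-class] for the image.
#' @param binarized a [BinarizedChoroid-class] from [niblackBinarize()].
#' @param AL axial length, mm (drives the lateral correction).
#' @param regions optional region table from [partitionRegions()]; defaults
#'   to the grid for the image's meridian and laterality.
#' @return list of class `"RegionalMetrics"`: `regions` (per-region
#'   data.frame), `meridian` (one-row data.frame of section aggregates),
#'   `factor` (Bennett factor used), `meridian_name`, `laterality`, `eye_id`.
#' @export
computeMetrics <- function(image, boundaries, binarized, AL,
                           regions = NULL) {
  stopifnot(is(image, "BScan"), is(boundaries, "ChoroidBoundaries"),
            is(binarized, "BinarizedChoroid"))
  if (is.null(regions))
    regions <- partitionRegions(meridian(image), laterality(image))
  f <- lateralFactor(AL)
  m <- pixels(image)
  w <- ncol(m)
  colw <- lateralSpacing(image) * f / 1000            # true mm per column
  x <- (seq_len(w) - foveaCol(image)) * colw          # column centers, mm
  pxArea <- f * lateralSpacing(image) * axialSpacing(image) * 1e-6  # mm^2
  v <- validCols(boundaries) & validCols(binarized)
  tpx <- bandThicknessPx(boundaries)
  lab <- choroidLabels(binarized)
  lumCol <- colSums(lab == 2L)
  strCol <- colSums(lab == 1L)

  out <- regions
  out$n_cols <- out$n_valid <- 0L
  out$ChT_um <- out$LA_mm2 <- out$SA_mm2 <- out$TCA_mm2 <- out$CVI <-
    out$LA_norm_mm2 <- out$SA_norm_mm2 <- NA_real_
  out$clamped_fraction <- 0
  for (i in seq_len(nrow(regions))) {
    inReg <- x >= regions$a_mm[i] & x < regions$b_mm[i]
    out$n_cols[i] <- sum(inReg)
    coverLo <- max(regions$a_mm[i], x[1L] - colw / 2)
    coverHi <- min(regions$b_mm[i], x[w] + colw / 2)
    out$clamped_fraction[i] <-
      max(0, 1 - max(0, coverHi - coverLo) / regions$width_mm[i])
    sel <- inReg & v
    out$n_valid[i] <- sum(sel)
    if (!any(sel)) next
    out$ChT_um[i] <- mean(tpx[sel]) * axialSpacing(image)
    la <- sum(lumCol[sel]) * pxArea
    sa <- sum(strCol[sel]) * pxArea
    out$LA_mm2[i] <- la; out$SA_mm2[i] <- sa; out$TCA_mm2[i] <- la + sa
    out$CVI[i] <- if (la + sa > 0) la / (la + sa) else NA_real_
    out$LA_norm_mm2[i] <- la / regions$normalize[i]
    out$SA_norm_mm2[i] <- sa / regions$normalize[i]
  }
  if (any(out$clamped_fraction > 1e-6))
    warning("section does not cover the full +/- 3 mm window; ",
            "clamped fractions reported per region")

  inWin <- x >= -3 & x < 3
  sel <- inWin & v
  mer <- data.frame(ChT_um = NA_real_, LA_mm2 = NA_real_, SA_mm2 = NA_real_,
                    TCA_mm2 = NA_real_, CVI = NA_real_,
                    n_cols = sum(inWin), n_valid = sum(sel),
                    valid_fraction = ifelse(sum(inWin) > 0,
                                            sum(sel) / sum(inWin), NA_real_))
  if (any(sel)) {
    mer$ChT_um <- mean(tpx[sel]) * axialSpacing(image)
    mer$LA_mm2 <- sum(lumCol[sel]) * pxArea
    mer$SA_mm2 <- sum(strCol[sel]) * pxArea
    mer$TCA_mm2 <- mer$LA_mm2 + mer$SA_mm2
    mer$CVI <- if (mer$TCA_mm2 > 0) mer$LA_mm2 / mer$TCA_mm2 else NA_real_
  }
  structure(list(regions = out, meridian = mer, factor = f,
                 meridian_name = meridian(image),
                 laterality = laterality(image), eye_id = eyeId(image)),
            class = "RegionalMetrics")
}

#' Flatten per-meridian metrics into one eye-level row
#'
#' Combines the vertical and horizontal [computeMetrics()] results of one
#' eye into a single named row matching the cohort-table schema: meridian
#' aggregates (`ChT_V`, `LA_V`, `SA_V`, `TCA_V`, `CVI_V` and `_H`
#' counterparts; areas in mm^2 are section totals, ChT in micrometers) and
#' per-region values (`ChT_N2`, `LA_N2`, ..., with the foveal C region
#' disambiguated as `C_V` / `C_H`; `*_norm` columns carry the perifoveal
#' width normalization). Regions or meridians not supplied are NA-flagged.
#'
#' @param vertical,horizontal `"RegionalMetrics"` results (either may be
#'   NULL).
#' @param eyeId identifier for the row; defaults to the first input's.
#' @return one-row data.frame.
#' @export
summarizeEye <- function(vertical = NULL, horizontal = NULL, eyeId = NULL) {
  if (is.null(vertical) && is.null(horizontal))
    stop("at least one meridian must be supplied")
  if (is.null(eyeId))
    eyeId <- if (!is.null(vertical)) vertical$eye_id else horizontal$eye_id
  row <- list(eye_id = eyeId)
  allRegions <- c("C_V", "S1", "S2", "I1", "I2", "C_H", "T1", "T2", "N1", "N2")
  for (side in list(list(m = vertical, suf = "V"),
                    list(m = horizontal, suf = "H"))) {
    suf <- side$suf
    if (is.null(side$m)) {
      row[paste0(c("ChT_", "LA_", "SA_", "TCA_", "CVI_", "valid_fraction_"),
                 suf)] <- NA_real_
      next
    }
    mm <- side$m$meridian
    row[[paste0("ChT_", suf)]] <- mm$ChT_um
    row[[paste0("LA_", suf)]] <- mm$LA_mm2
    row[[paste0("SA_", suf)]] <- mm$SA_mm2
    row[[paste0("TCA_", suf)]] <- mm$TCA_mm2
    row[[paste0("CVI_", suf)]] <- mm$CVI
    row[[paste0("valid_fraction_", suf)]] <- mm$valid_fraction
    rg <- side$m$regions
    for (i in seq_len(nrow(rg))) {
      key <- if (rg$name[i] == "C") paste0("C_", suf) else rg$name[i]
      row[[paste0("ChT_", key)]] <- rg$ChT_um[i]
      row[[paste0("LA_", key)]] <- rg$LA_mm2[i]
      row[[paste0("SA_", key)]] <- rg$SA_mm2[i]
      row[[paste0("CVI_", key)]] <- rg$CVI[i]
      row[[paste0("LA_", key, "_norm")]] <- rg$LA_norm_mm2[i]
      row[[paste0("SA_", key, "_norm")]] <- rg$SA_norm_mm2[i]
    }
  }
  for (r in allRegions) {   # NA-flag regions from a missing meridian
    for (p in c("ChT_", "LA_", "SA_", "CVI_")) {
      nm <- paste0(p, r)
      if (is.null(row[[nm]])) row[[nm]] <- NA_real_
    }
    for (nm in paste0(c("LA_", "SA_"), r, "_norm"))
      if (is.null(row[[nm]])) row[[nm]] <- NA_real_
  }
  as.data.frame(row, stringsAsFactors = FALSE)
}
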