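#' Quantify choroidal metrics for a batch of eyes
#'
#' Runs the imaging pipeline — read (or simulate-supplied) B-scan, ingest or
#' baseline-segment boundaries, Niblack-binarize, magnification-correct,
#' compute regional metrics — for every row of a run table, and flattens the
#' results to one row per eye. Per-eye failures (unreadable image, missing
#' axial length, degenerate band) are logged and do not abort the batch.
#'
#' @param runTable data.frame with one row per eye-meridian and columns:
#'   `eye_id`, `meridian` ("vertical"/"horizontal"), `laterality`
#'   ("OD"/"OS"), `image` (TIFF path), `boundaries` (CSV/PNG path, or NA to
#'   baseline-segment), `AL` (mm), `fovea_col` (1-based), `axial_um_per_px`,
#'   `lateral_um_per_px`.
#' @param config a [binarizationConfig()].
#' @param outDir optional directory; when given, writes `eyes.csv` (wide
#'   per-eye metrics), `regions.csv` (long per-region metrics) and
#'   `manifest.json` (full resolved configuration).
#' @return list with `eyes` (one row per eye, [summarizeEye()] schema),
#'   `regions` (long per-region table), `failures` (data.frame: eye_id,
#'   meridian, message), `n_failed`, `manifest`.
#' @export
runQuantify <- function(runTable, config = binarizationConfig(),
                        outDir = NULL) {
  need <- c("eye_id", "meridian", "laterality", "image", "boundaries", "AL",
            "fovea_col", "axial_um_per_px", "lateral_um_per_px")
  miss <- setdiff(need, names(runTable))
  if (length(miss)) stop("run table lacks column(s): ",
                         paste(miss, collapse = ", "))
  perScan <- list(); failures <- list(); regionsLong <- list()
  for (i in seq_len(nrow(runTable))) {
    row <- runTable[i, ]
    res <- tryCatch({
      if (is.na(row$AL)) stop("missing axial length")
      img <- readBScanTiff(row$image, axialSpacing = row$axial_um_per_px,
                           lateralSpacing = row$lateral_um_per_px,
                           foveaCol = row$fovea_col,
                           meridian = row$meridian,
                           laterality = row$laterality, eyeId = row$eye_id)
      bnd <- if (is.na(row$boundaries)) baselineSegment(img)
      else readBoundaries(row$boundaries)
      bin <- niblackBinarize(img, bnd, config)
      computeMetrics(img, bnd, bin, AL = row$AL)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[[length(failures) + 1L]] <-
        data.frame(eye_id = row$eye_id, meridian = row$meridian,
                   message = conditionMessage(res))
    } else {
      key <- paste(row$eye_id, row$meridian, sep = "::")
      perScan[[key]] <- res
      rg <- res$regions
      rg$eye_id <- row$eye_id; rg$meridian <- row$meridian
      rg$AL <- row$AL; rg$factor <- res$factor
      regionsLong[[key]] <- rg
    }
  }
  eyeIds <- unique(runTable$eye_id)
  eyes <- do.call(rbind, lapply(eyeIds, function(id) {
    v <- perScan[[paste(id, "vertical", sep = "::")]]
    h <- perScan[[paste(id, "horizontal", sep = "::")]]
    if (is.null(v) && is.null(h)) return(NULL)
    summarizeEye(vertical = v, horizontal = h, eyeId = id)
  }))
  failures <- if (length(failures)) do.call(rbind, failures)
  else data.frame(eye_id = character(), meridian = character(),
                  message = character())
  manifest <- list(config = unclass(config), n_scans = nrow(runTable),
                   n_failed = nrow(failures),
                   package_version = as.character(
                     utils::packageVersion("ChoroidCVI")))
  regions <- if (length(regionsLong)) do.call(rbind, regionsLong) else NULL
  if (!is.null(regions)) rownames(regions) <- NULL
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(eyes, file.path(outDir, "eyes.csv"), row.names = FALSE)
    if (!is.null(regions))
      utils::write.csv(regions, file.path(outDir, "regions.csv"),
                       row.names = FALSE)
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  list(eyes = eyes, regions = regions, failures = failures,
       n_failed = nrow(failures), manifest = manifest)
}

#' Run the cohort analysis suite
#'
#' Applies exclusion flags, then produces the full analysis set on the
#' survivors: eye-clustered group comparisons of the meridian metrics with
#' Bonferroni pairwise contrasts, standardized logistic models for DCA
#' presence (one per predictor), linear MD models in all / non-PM / PM eyes
#' (skipped with a warning if no usable `MD` column), and the
#' (optionally age-stratified) ROC/Youden cut-off table.
#'
#' @param cohort eye-level data.frame (see [simulateCohort()] for the
#'   schema; metrics columns from [runQuantify()] merge in by eye).
#' @param comparisonOutcomes metric columns for the group comparisons.
#' @param logisticPredictors predictor columns for the DCA models.
#' @param mdPredictors predictor columns for the MD models.
#' @param rocPredictors predictor columns for the cut-off table.
#' @param strata logical; stratify the ROC table by age.
#' @param outDir optional directory for `comparisons.csv`, `logistic.csv`,
#'   `linear.csv`, `roc.csv`, `exclusions.csv` and `manifest.json`.
#' @return list with `exclusions`, `comparisons`, `logistic`, `linear`,
#'   `roc`, `manifest`.
#' @export
runAnalyze <- function(cohort,
                       comparisonOutcomes = c("ChT_V", "LA_V", "SA_V",
                                              "CVI_V"),
                       logisticPredictors = c("ChT_V", "LA_V", "SA_V",
                                              "CVI_V", "LA_N2", "SA_N2"),
                       mdPredictors = c("LA_V", "SA_V"),
                       rocPredictors = c("ChT_V", "LA_V", "SA_V", "ChT_N2",
                                         "LA_N2", "SA_N2"),
                       strata = TRUE, outDir = NULL) {
  excl <- applyExclusions(cohort)
  d <- excl$cohort

  comparisons <- do.call(rbind, lapply(
    intersect(comparisonOutcomes, names(d)), function(oc) {
      cg <- compareGroups(d, oc)
      cbind(outcome = oc, cg$contrasts)
    }))

  logistic <- do.call(rbind, lapply(
    intersect(logisticPredictors, names(d)), function(pr)
      fitDcaLogistic(d, pr)))

  linear <- NULL
  if ("MD" %in% names(d) && any(!is.na(d$MD))) {
    linear <- do.call(rbind, unlist(recursive = FALSE, lapply(
      intersect(mdPredictors, names(d)), function(pr)
        lapply(c("all", "nonpm", "pm"), function(ss)
          tryCatch(fitMdLinear(d, pr, subset = ss),
                   error = function(e) NULL)))))
  } else warning("no usable MD column: linear MD models skipped")

  roc <- ageStratifiedTable(d, predictors = rocPredictors, strata = strata)

  manifest <- list(n_input = excl$n_input, n_analyzed = excl$n_kept,
                   strata = strata,
                   comparison_outcomes = comparisonOutcomes,
                   logistic_predictors = logisticPredictors,
                   md_predictors = mdPredictors,
                   roc_predictors = rocPredictors,
                   standardization = "sample mean/SD over analyzed eyes",
                   package_version = as.character(
                     utils::packageVersion("ChoroidCVI")))
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(excl$ledger, file.path(outDir, "exclusions.csv"),
                     row.names = FALSE)
    utils::write.csv(comparisons, file.path(outDir, "comparisons.csv"),
                     row.names = FALSE)
    utils::write.csv(logistic, file.path(outDir, "logistic.csv"),
                     row.names = FALSE)
    if (!is.null(linear))
      utils::write.csv(linear, file.path(outDir, "linear.csv"),
                       row.names = FALSE)
    utils::write.csv(roc, file.path(outDir, "roc.csv"), row.names = FALSE)
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  list(exclusions = excl, comparisons = comparisons, logistic = logistic,
       linear = linear, roc = roc, manifest = manifest)
}
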