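#' ROC analysis with Youden-optimal cut-off and DeLong interval
#'
#' Computes the ROC area for one continuous predictor against a binary
#' disease label, picks the cut-off maximizing the Youden index
#' J = sensitivity + specificity - 1, and reports a DeLong standard error
#' and 95% confidence interval for the AUC.
#'
#' The orientation is chosen so that AUC >= 0.5 (for choroidal thickness and
#' areas, lower values indicate disease); it can be forced with
#' `direction`. The AUC is the pairwise concordance statistic (ties counted
#' half). Candidate cut-offs are the midpoints between consecutive sorted
#' unique predictor values, plus open ends; ties in J are broken in favor of
#' higher sensitivity, then the smaller cut-off, and the reported cut-off is
#' clamped to the observed predictor range. The p-value tests AUC = 0.5 with
#' the DeLong variance.
#'
#' @param values numeric predictor.
#' @param labels logical (or 0/1) disease indicator, TRUE = diseased.
#' @param predictor name used in the output row.
#' @param stratum stratum label for the output row.
#' @param direction `"auto"` (default), `"lower"` (value < cutoff indicates
#'   disease) or `"higher"`.
#' @return one-row data.frame of class `"ROCResult"`: predictor, stratum,
#'   orientation, n_pos, n_neg, auc, se, ci_low, ci_high, p, cutoff,
#'   sensitivity and specificity (percent), youden (proportion scale).
#' @examples
#' rocCutoff(c(0.1, 0.4, 0.35, 0.8), c(FALSE, FALSE, TRUE, TRUE),
#'           direction = "higher")
#' @export
rocCutoff <- function(values, labels, predictor = "x", stratum = "All",
                      direction = c("auto", "lower", "higher")) {
  direction <- match.arg(direction)
  ok <- !is.na(values) & !is.na(labels)
  values <- values[ok]; labels <- as.logical(labels[ok])
  nPos <- sum(labels); nNeg <- sum(!labels)
  if (nPos == 0L || nNeg == 0L)
    stop("both classes must be present (", nPos, " diseased, ", nNeg,
         " healthy)")
  pos <- values[labels]; neg <- values[!labels]
  aucHigher <- .concordanceAUC(pos, neg)
  orientation <- switch(direction,
                        auto = if (aucHigher >= 0.5) "higher" else "lower",
                        lower = "lower", higher = "higher")
  s <- if (orientation == "higher") values else -values
  sPos <- s[labels]; sNeg <- s[!labels]
  auc <- .concordanceAUC(sPos, sNeg)

  # DeLong: variance of the AUC from the placement values
  v10 <- vapply(sPos, function(x)
    (sum(sNeg < x) + 0.5 * sum(sNeg == x)) / nNeg, numeric(1))
  v01 <- vapply(sNeg, function(x)
    (sum(sPos > x) + 0.5 * sum(sPos == x)) / nPos, numeric(1))
  se <- sqrt(stats::var(v10) / nPos + stats::var(v01) / nNeg)
  ciLow <- max(0, auc - 1.96 * se)
  ciHigh <- min(1, auc + 1.96 * se)
  p <- if (se > 0) 2 * stats::pnorm(-abs((auc - 0.5) / se)) else NA_real_

  u <- sort(unique(s))
  cand <- if (length(u) > 1L) (u[-length(u)] + u[-1L]) / 2 else u
  cand <- c(u[1L] - 1, cand, u[length(u)] + 1)
  sens <- vapply(cand, function(cc) mean(sPos > cc), numeric(1))
  spec <- vapply(cand, function(cc) mean(sNeg <= cc), numeric(1))
  J <- sens + spec - 1
  best <- which(J == max(J))
  if (length(best) > 1L) best <- best[sens[best] == max(sens[best])]
  if (length(best) > 1L) {   # smaller cut-off in original predictor units
    orig <- if (orientation == "higher") cand[best] else -cand[best]
    best <- best[which.min(orig)]
  } else best <- best[1L]
  cutoff <- if (orientation == "higher") cand[best] else -cand[best]
  cutoff <- min(max(cutoff, min(values)), max(values))

  out <- data.frame(predictor = predictor, stratum = stratum,
                    orientation = orientation, n_pos = nPos, n_neg = nNeg,
                    auc = auc, se = se, ci_low = ciLow, ci_high = ciHigh,
                    p = p, cutoff = cutoff,
                    sensitivity = 100 * sens[best],
                    specificity = 100 * spec[best],
                    youden = J[best])
  class(out) <- c("ROCResult", class(out))
  out
}

# pairwise concordance AUC, ties counted half (rank formulation)
.concordanceAUC <- function(pos, neg) {
  r <- rank(c(pos, neg))
  np <- length(pos); nn <- length(neg)
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nn)
}

#' Age-stratified ROC cut-off table
#'
#' Runs [rocCutoff()] for each predictor overall and within the age strata
#' 18 <= age <= 30, 30 < age <= 40, 40 < age <= 50 and 50 < age <= 60, with
#' pathological myopia (DCA, `dca == TRUE`) as the disease label. A stratum
#' that is empty or one-class yields a missing (NA) row rather than an
#' error.
#'
#' @param cohort data.frame with `age`, `dca` and the predictor columns.
#' @param predictors metric columns to evaluate.
#' @param strata logical; `FALSE` restricts the table to the "All" rows.
#' @param direction passed to [rocCutoff()] (choroidal metrics: lower value
#'   indicates disease; `"auto"` resolves this from the data).
#' @return data.frame of stacked `"ROCResult"` rows (NA-filled where a
#'   stratum was unusable).
#' @export
ageStratifiedTable <- function(cohort,
                               predictors = c("ChT_V", "LA_V", "SA_V",
                                              "ChT_N2", "LA_N2", "SA_N2"),
                               strata = TRUE, direction = "auto") {
  bounds <- list(All = c(-Inf, Inf))
  if (strata)
    bounds <- c(bounds, list(
      "18<=Age<=30" = c(18, 30), "30<Age<=40" = c(30, 40),
      "40<Age<=50" = c(40, 50), "50<Age<=60" = c(50, 60)))
  rows <- list()
  for (pred in intersect(predictors, names(cohort))) {
    for (snm in names(bounds)) {
      b <- bounds[[snm]]
      sel <- if (snm == "All") rep(TRUE, nrow(cohort))
      else if (snm == "18<=Age<=30") cohort$age >= 18 & cohort$age <= 30
      else cohort$age > b[1] & cohort$age <= b[2]
      sub <- cohort[sel & !is.na(cohort$age), , drop = FALSE]
      row <- tryCatch(
        rocCutoff(sub[[pred]], sub$dca, predictor = pred, stratum = snm,
                  direction = direction),
        error = function(e)
          data.frame(predictor = pred, stratum = snm,
                     orientation = NA_character_,
                     n_pos = sum(sub$dca %in% TRUE),
                     n_neg = sum(sub$dca %in% FALSE),
                     auc = NA_real_, se = NA_real_, ci_low = NA_real_,
                     ci_high = NA_real_, p = NA_real_, cutoff = NA_real_,
                     sensitivity = NA_real_, specificity = NA_real_,
                     youden = NA_real_))
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
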