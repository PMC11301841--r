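#' Apply exclusion flags to a cohort table
#'
#' Removes eyes carrying any `excl_*` flag and returns an itemized ledger:
#' removals per reason and per eye side. One eye may carry several reasons,
#' so per-reason counts may sum to more than the eyes removed; the survivor
#' count always equals input minus flagged eyes.
#'
#' @param cohort data.frame with logical `excl_*` columns and an `eye`
#'   column (`"OD"`/`"OS"`).
#' @return list with `cohort` (survivors), `ledger` (data.frame: reason,
#'   OD, OS, total), `n_input`, `n_removed`, `n_kept`.
#' @export
applyExclusions <- function(cohort) {
  flagCols <- grep("^excl_", names(cohort), value = TRUE)
  if (!length(flagCols)) stop("no 'excl_*' flag columns present")
  flags <- as.matrix(cohort[flagCols]) == TRUE
  removed <- rowSums(flags, na.rm = TRUE) > 0
  ledger <- data.frame(
    reason = sub("^excl_", "", flagCols),
    OD = as.integer(colSums(flags & cohort$eye == "OD", na.rm = TRUE)),
    OS = as.integer(colSums(flags & cohort$eye == "OS", na.rm = TRUE)))
  ledger$total <- ledger$OD + ledger$OS
  ledger <- rbind(ledger,
                  data.frame(reason = "eyes_removed",
                             OD = sum(removed & cohort$eye == "OD"),
                             OS = sum(removed & cohort$eye == "OS"),
                             total = sum(removed)))
  ledger$OD <- as.integer(ledger$OD)
  ledger$OS <- as.integer(ledger$OS)
  ledger$total <- as.integer(ledger$total)
  rownames(ledger) <- NULL
  list(cohort = cohort[!removed, , drop = FALSE], ledger = ledger,
       n_input = nrow(cohort), n_removed = sum(removed),
       n_kept = sum(!removed))
}

# Gaussian GEE with exchangeable working correlation and robust (sandwich)
# covariance. Clusters are rows sharing `id`; cluster sizes 1..m supported.
.geeExchangeable <- function(formula, data, id, maxit = 25L, tol = 1e-10) {
  vars <- c(all.vars(formula), id)
  data <- data[stats::complete.cases(data[vars]), , drop = FALSE]
  mf <- stats::model.frame(formula, data = data)
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  y <- stats::model.response(mf)
  cl <- factor(data[[id]])
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("singular design; collinear term(s): ",
         paste(aliased, collapse = ", "))
  }
  N <- nrow(X); p <- ncol(X)
  beta <- qr.coef(qrX, y)
  idx <- split(seq_len(N), cl)
  alpha <- 0
  for (iter in seq_len(maxit)) {
    r <- y - drop(X %*% beta)
    sigma2 <- sum(r^2) / (N - p)
    num <- 0; npair <- 0
    for (ii in idx) {
      if (length(ii) < 2L) next
      e <- r[ii] / sqrt(sigma2)
      s <- sum(e)
      num <- num + (s^2 - sum(e^2)) / 2
      npair <- npair + length(ii) * (length(ii) - 1L) / 2
    }
    alpha <- if (npair > p) max(0, min(0.99, num / (npair - p))) else 0
    A <- matrix(0, p, p); bvec <- numeric(p)
    for (ii in idx) {
      ni <- length(ii)
      Ri <- matrix(alpha, ni, ni); diag(Ri) <- 1
      Wi <- solve(Ri)
      Xi <- X[ii, , drop = FALSE]
      A <- A + crossprod(Xi, Wi %*% Xi)
      bvec <- bvec + crossprod(Xi, Wi %*% y[ii])
    }
    betaNew <- drop(solve(A, bvec))
    done <- max(abs(betaNew - beta)) < tol
    beta <- betaNew
    if (done) break
  }
  r <- y - drop(X %*% beta)
  A <- matrix(0, p, p)
  for (ii in idx) {
    ni <- length(ii)
    Ri <- matrix(alpha, ni, ni); diag(Ri) <- 1
    Wi <- solve(Ri)
    Xi <- X[ii, , drop = FALSE]
    A <- A + crossprod(Xi, Wi %*% Xi)
  }
  Ainv <- solve(A)
  # Mancl-DeRouen bias-corrected sandwich: inflate each cluster's residual
  # by (I - H_i)^{-1} before forming the meat
  B <- matrix(0, p, p)
  for (ii in idx) {
    ni <- length(ii)
    Ri <- matrix(alpha, ni, ni); diag(Ri) <- 1
    Wi <- solve(Ri)
    Xi <- X[ii, , drop = FALSE]
    Hi <- Xi %*% Ainv %*% crossprod(Xi, Wi)
    eAdj <- solve(diag(ni) - Hi, r[ii])
    u <- crossprod(Xi, Wi %*% eAdj)
    B <- B + tcrossprod(u)
  }
  V <- Ainv %*% B %*% Ainv
  names(beta) <- colnames(X)
  dimnames(V) <- list(colnames(X), colnames(X))
  list(coefficients = beta, vcov = V, alpha = alpha, n = N,
       n_clusters = length(idx), df = length(idx) - p,
       X = X, terms = attr(mf, "terms"))
}

#' Eye-clustered group comparison with Bonferroni pairwise contrasts
#'
#' Fits a marginal linear model of a continuous outcome on the maculopathy
#' category plus adjusters, with subject-level clustering (exchangeable
#' working correlation, robust sandwich standard errors with the
#' Mancl-DeRouen small-sample bias correction and a t reference on
#' clusters-minus-parameters degrees of freedom), then forms the three
#' pairwise group contrasts with Bonferroni-adjusted p-values (raw p x 3,
#' capped at 1). With one eye per subject and no adjusters the coefficients
#' coincide with ordinary least squares.
#'
#' @param cohort data.frame with the outcome, `category`, adjusters and a
#'   subject id column.
#' @param outcome name of the outcome column.
#' @param adjusters character vector of adjustment covariates (default age
#'   and AL).
#' @param group grouping column (default `"category"`).
#' @param id cluster (subject) id column.
#' @return list with `means` (adjusted marginal group means at the average
#'   adjuster values), `contrasts` (data.frame: contrast, estimate, SE, z,
#'   p, p_adj), `alpha` (working correlation), `n`.
#' @export
compareGroups <- function(cohort, outcome, adjusters = c("age", "AL"),
                          group = "category", id = "subject_id") {
  vars <- c(outcome, group, adjusters, id)
  miss <- setdiff(vars, names(cohort))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  d <- cohort[stats::complete.cases(cohort[vars]), vars, drop = FALSE]
  d[[group]] <- factor(d[[group]])
  lev <- levels(d[[group]])
  if (length(lev) < 2L) stop("need at least two groups")
  if (any(table(d[[group]]) < 2L)) stop("each group needs >= 2 observations")
  rownames(d) <- NULL
  fml <- stats::reformulate(c(group, adjusters), response = outcome)
  fit <- .geeExchangeable(fml, d, id = id)
  cf <- fit$coefficients

  # adjusted means: group effect + intercept + adjusters at their means
  base <- cf[["(Intercept)"]] +
    sum(vapply(adjusters, function(a) cf[[a]] * mean(d[[a]]), numeric(1)))
  eff <- c(0, vapply(lev[-1], function(l)
    cf[[paste0(group, l)]], numeric(1)))
  means <- data.frame(group = lev, adjusted_mean = base + eff,
                      n = as.integer(table(d[[group]])))

  pairs <- utils::combn(lev, 2L)
  res <- lapply(seq_len(ncol(pairs)), function(k) {
    g1 <- pairs[1L, k]; g2 <- pairs[2L, k]
    cvec <- stats::setNames(numeric(length(cf)), names(cf))
    if (g2 != lev[1L]) cvec[paste0(group, g2)] <- 1
    if (g1 != lev[1L]) cvec[paste0(group, g1)] <- -1
    est <- sum(cvec * cf)
    se <- sqrt(drop(t(cvec) %*% fit$vcov %*% cvec))
    z <- est / se
    p <- 2 * stats::pt(-abs(z), df = max(fit$df, 1L))
    data.frame(contrast = paste(g2, "-", g1), estimate = est, SE = se,
               z = z, p = p)
  })
  contrasts <- do.call(rbind, res)
  m <- nrow(contrasts)
  contrasts$p_adj <- pmin(1, contrasts$p * m)
  list(means = means, contrasts = contrasts, alpha = fit$alpha, n = fit$n,
       coefficients = cf, vcov = fit$vcov)
}

# z-standardize over the analyzed eyes (sample mean/SD)
.zscale <- function(x) (x - mean(x)) / stats::sd(x)

#' Standardized logistic model for DCA presence
#'
#' Regresses the DCA indicator on one standardized choroidal predictor plus
#' standardized age and axial length and gender, with subject-clustered
#' robust standard errors. Continuous variables are Z-scored over the
#' analyzed eyes, so the odds ratio is per one sample SD of the predictor
#' and is invariant to affine rescaling of the raw predictor.
#'
#' @param cohort data.frame with `dca`, the predictor, `age`, `AL`,
#'   `gender` and the subject id.
#' @param predictor name of the choroidal metric column.
#' @param id cluster (subject) id column.
#' @return data.frame of class `"RegressionResult"`: term, B (log-odds per
#'   SD for continuous terms), SE (cluster-robust), OR, CI bounds, p, n.
#' @export
fitDcaLogistic <- function(cohort, predictor, id = "subject_id") {
  vars <- c("dca", predictor, "age", "AL", "gender", id)
  miss <- setdiff(vars, names(cohort))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  d <- cohort[stats::complete.cases(cohort[vars]), vars, drop = FALSE]
  if (length(unique(d$dca)) < 2L)
    stop("both outcome classes must be present")
  if (stats::sd(d[[predictor]]) == 0) stop("predictor is constant")
  d$z_pred <- .zscale(d[[predictor]])
  d$z_age <- .zscale(d$age)
  d$z_AL <- .zscale(d$AL)
  fit <- stats::glm(dca ~ z_pred + z_age + z_AL + gender, data = d,
                    family = stats::binomial())
  if (!fit$converged || any(abs(stats::coef(fit)) > 15))
    stop("perfect or quasi-perfect separation detected for '", predictor,
         "'")
  V <- sandwich::vcovCL(fit, cluster = d[[id]])
  b <- stats::coef(fit)
  se <- sqrt(diag(V))
  z <- b / se
  p <- 2 * stats::pnorm(-abs(z))
  out <- data.frame(term = names(b), B = unname(b), SE = unname(se),
                    OR = exp(unname(b)),
                    OR_low = exp(unname(b - 1.96 * se)),
                    OR_high = exp(unname(b + 1.96 * se)),
                    p = unname(p), n = nrow(d), predictor = predictor)
  class(out) <- c("RegressionResult", class(out))
  out
}

#' Linear model for visual-field mean deviation
#'
#' Regresses MD (dB) on age, height, axial length, corneal curvature and one
#' choroidal predictor, on reliable visual-field eyes of the requested
#' subset, with subject-clustered robust standard errors. Reports
#' unstandardized B with SE and 95% CI, the standardized beta
#' (B x SD(x) / SD(MD)), and p per term.
#'
#' @param cohort data.frame (needs `MD`, `vf_reliable`, `category`, the
#'   covariates and the subject id).
#' @param predictor `"LA_V"`, `"SA_V"` or another metric column.
#' @param subset `"all"`, `"nonpm"` (C0 + C1) or `"pm"` (C2).
#' @param id cluster (subject) id column.
#' @return data.frame of class `"RegressionResult"`: term, B, SE, beta,
#'   CI bounds, p, n, subset.
#' @export
fitMdLinear <- function(cohort, predictor = "LA_V",
                        subset = c("all", "nonpm", "pm"),
                        id = "subject_id") {
  subset <- match.arg(subset)
  vars <- c("MD", "age", "height", "AL", "corneal_curvature", predictor,
            "category", "vf_reliable", id)
  miss <- setdiff(vars, names(cohort))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  d <- cohort[cohort$vf_reliable %in% TRUE, vars, drop = FALSE]
  d <- switch(subset,
              all = d,
              nonpm = d[d$category %in% c("C0", "C1"), , drop = FALSE],
              pm = d[d$category == "C2", , drop = FALSE])
  d <- d[stats::complete.cases(d), , drop = FALSE]
  fml <- stats::reformulate(c("age", "height", "AL", "corneal_curvature",
                              predictor), response = "MD")
  nterms <- 6L
  if (nrow(d) < nterms + 2L)
    stop("too few rows (", nrow(d), ") for ", nterms, " model terms")
  fit <- stats::lm(fml, data = d)
  V <- sandwich::vcovCL(fit, cluster = d[[id]])
  b <- stats::coef(fit)
  se <- sqrt(diag(V))
  sdy <- stats::sd(d$MD)
  beta <- vapply(names(b), function(t)
    if (t == "(Intercept)") NA_real_ else
      unname(b[t]) * stats::sd(d[[t]]) / sdy, numeric(1))
  z <- b / se
  p <- 2 * stats::pnorm(-abs(z))
  out <- data.frame(term = names(b), B = unname(b), SE = unname(se),
                    beta = unname(beta),
                    CI_low = unname(b - 1.96 * se),
                    CI_high = unname(b + 1.96 * se),
                    p = unname(p), n = nrow(d), subset = subset,
                    predictor = predictor)
  class(out) <- c("RegressionResult", class(out))
  out
}
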