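test_that("the four-point worked example gives AUC 0.75", {
  r <- rocCutoff(c(0.1, 0.4, 0.35, 0.8), c(FALSE, FALSE, TRUE, TRUE),
                 direction = "higher")
  expect_equal(r$auc, 0.75)
  expect_equal(r$youden, r$sensitivity / 100 + r$specificity / 100 - 1)
})

test_that("perfect separation with low values diseased gives AUC and J of 1", {
  r <- rocCutoff(c(1, 2, 3, 10, 11, 12), c(TRUE, TRUE, TRUE, FALSE, FALSE,
                                           FALSE))
  expect_identical(r$orientation, "lower")
  expect_equal(r$auc, 1)
  expect_equal(r$youden, 1)
  expect_equal(r$sensitivity, 100)
  expect_equal(r$specificity, 100)
  expect_gt(r$cutoff, 3); expect_lt(r$cutoff, 10)
})

test_that("AUC equals brute-force pair enumeration on random data", {
  set.seed(55)
  for (rep in 1:12) {
    n <- sample(10:120, 1)
    lab <- c(TRUE, FALSE, stats::runif(n - 2) < 0.4)
    val <- round(stats::rnorm(n, ifelse(lab, 1, 0)), 1)  # induces ties
    r <- rocCutoff(val, lab, direction = "higher")
    expect_equal(r$auc, bruteAUC(val, lab), tolerance = 1e-12)
  }
})

test_that("AUC and DeLong variance agree with an independent implementation", {
  set.seed(9)
  val <- stats::rnorm(150)
  lab <- stats::runif(150) < stats::plogis(1.5 * val)
  r <- rocCutoff(val, lab, direction = "higher")
  pr <- pROC::roc(response = lab, predictor = val, direction = "<",
                  quiet = TRUE)
  expect_equal(r$auc, as.numeric(pROC::auc(pr)), tolerance = 1e-12)
  expect_equal(r$se^2, as.numeric(pROC::var(pr)), tolerance = 1e-10)
})

test_that("Youden identity and cutoff-in-range hold over random inputs", {
  set.seed(101)
  for (rep in 1:10) {
    n <- sample(20:200, 1)
    lab <- c(TRUE, FALSE, stats::runif(n - 2) < 0.3)
    val <- stats::rnorm(n, ifelse(lab, -0.8, 0))
    r <- rocCutoff(val, lab)
    expect_equal(r$youden, r$sensitivity / 100 + r$specificity / 100 - 1,
                 tolerance = 1e-12)
    expect_gte(r$cutoff, min(val)); expect_lte(r$cutoff, max(val))
    expect_gte(r$auc, 0.5)
  }
})

test_that("one-class inputs raise an explicit error", {
  expect_error(rocCutoff(1:5, rep(TRUE, 5)), "both classes")
})

test_that("stratified rows equal direct calls on manual subsets", {
  sim <- simulateCohort(cohortSimConfig(n_subjects = 400, seed = 88))
  d <- sim$cohort
  tab <- ageStratifiedTable(d, predictors = "ChT_V")
  sub <- d[d$age > 30 & d$age <= 40, ]
  direct <- rocCutoff(sub$ChT_V, sub$dca, predictor = "ChT_V",
                      stratum = "30<Age<=40")
  row <- tab[tab$stratum == "30<Age<=40", ]
  expect_equal(row$auc, direct$auc)
  expect_equal(row$cutoff, direct$cutoff)
  expect_equal(row$youden, direct$youden)
})

test_that("strata outside the observed age range come back missing", {
  sim <- simulateCohort(cohortSimConfig(n_subjects = 200, seed = 12))
  d <- sim$cohort
  d$age <- stats::runif(nrow(d), 31, 40)        # only one stratum populated
  tab <- ageStratifiedTable(d, predictors = "ChT_V")
  expect_false(is.na(tab$auc[tab$stratum == "All"]))
  expect_false(is.na(tab$auc[tab$stratum == "30<Age<=40"]))
  expect_true(is.na(tab$auc[tab$stratum == "18<=Age<=30"]))
  expect_true(is.na(tab$auc[tab$stratum == "50<Age<=60"]))
  noStrata <- ageStratifiedTable(d, predictors = "ChT_V", strata = FALSE)
  expect_identical(unique(noStrata$stratum), "All")
})

test_that("shifted diseased distributions are detected in every stratum", {
  sim <- simulateCohort(cohortSimConfig(n_subjects = 500, seed = 61))
  d <- sim$cohort
  # impose a clean -60 um shift on C2 eyes over a common baseline
  base <- stats::rnorm(nrow(d), 180, 40)
  d$ChT_V <- ifelse(d$dca, base - 60, base)
  tab <- ageStratifiedTable(d, predictors = "ChT_V")
  expect_true(all(tab$auc[!is.na(tab$auc)] > 0.8))
})
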