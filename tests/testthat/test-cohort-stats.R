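test_that("the exclusion ledger accounts for every removed eye", {
  d <- makeExclusionCohort()
  res <- applyExclusions(d)
  expect_identical(res$n_input, 1446L)
  expect_identical(res$n_kept, 1418L)
  led <- res$ledger
  removed <- led[led$reason == "eyes_removed", ]
  expect_identical(removed$OD, 17L)
  expect_identical(removed$OS, 11L)
  # per-reason counts may exceed removed eyes (multi-reason eyes) but never
  # fall short of them
  expect_gte(sum(led$total[led$reason != "eyes_removed"]), removed$total)
  expect_identical(res$n_input - res$n_removed, nrow(res$cohort))
})

test_that("no flags means identity; all flags means empty", {
  d <- makeExclusionCohort()
  d[grep("^excl_", names(d))] <- FALSE
  res <- applyExclusions(d)
  expect_identical(res$cohort, d)
  d$excl_choroiditis <- TRUE
  res <- applyExclusions(d)
  expect_identical(nrow(res$cohort), 0L)
  expect_identical(res$ledger$total[res$ledger$reason == "eyes_removed"],
                   1446L)
})

test_that("one eye per subject without adjusters reduces to OLS", {
  set.seed(12)
  n <- 90
  d <- data.frame(subject_id = sprintf("P%03d", 1:n),
                  category = sample(c("C0", "C1", "C2"), n, replace = TRUE),
                  y = stats::rnorm(n, 100, 15))
  fit <- compareGroups(d, "y", adjusters = character(0))
  ols <- stats::lm(y ~ factor(category), data = d)
  expect_equal(unname(fit$coefficients), unname(stats::coef(ols)),
               tolerance = 1e-6)
  # adjusted means equal the raw group means in the balanced-model sense
  expect_equal(fit$means$adjusted_mean,
               as.numeric(tapply(d$y, d$category, mean)), tolerance = 1e-6)
})

test_that("pairwise p-values carry the Bonferroni factor of three", {
  sim <- simulateCohort(cohortSimConfig(n_subjects = 150, seed = 44))
  fit <- compareGroups(sim$cohort, "ChT_V")
  expect_identical(nrow(fit$contrasts), 3L)
  expect_equal(fit$contrasts$p_adj, pmin(1, fit$contrasts$p * 3))
  expect_true(all(fit$contrasts$p_adj >= fit$contrasts$p))
})

test_that("the exchangeable working correlation recovers the truth", {
  sim <- simulateCohort(cohortSimConfig(n_subjects = 600,
                                        intra_subject_correlation = 0.7,
                                        seed = 13))
  fit <- compareGroups(sim$cohort, "ChT_V")
  expect_gt(fit$alpha, 0.5)
  expect_lt(fit$alpha, 0.85)
})

test_that("singular designs raise an error naming the collinear term", {
  sim <- simulateCohort(cohortSimConfig(n_subjects = 60, seed = 2))
  d <- sim$cohort
  d$age_copy <- d$age
  expect_error(compareGroups(d, "ChT_V", adjusters = c("age", "age_copy")),
               "age_copy")
})

test_that("the DCA odds ratio is invariant to predictor rescaling", {
  sim <- simulateCohort(cohortSimConfig(n_subjects = 250, seed = 7))
  d <- sim$cohort
  f1 <- fitDcaLogistic(d, "LA_V")
  d$LA_V10 <- d$LA_V * 10
  f2 <- fitDcaLogistic(d, "LA_V10")
  expect_equal(f1$OR[f1$term == "z_pred"], f2$OR[f2$term == "z_pred"],
               tolerance = 1e-10)
  expect_equal(f1$SE[f1$term == "z_pred"], f2$SE[f2$term == "z_pred"],
               tolerance = 1e-10)
  # OR = exp(B) and ordered CI by construction
  expect_equal(f1$OR, exp(f1$B))
  expect_true(all(f1$OR_low <= f1$OR_high))
})

test_that("perfect separation is reported, not silently fitted", {
  sim <- simulateCohort(cohortSimConfig(n_subjects = 100, seed = 3))
  d <- sim$cohort
  d$sep <- ifelse(d$dca, 100, 0) + stats::runif(nrow(d))
  suppressWarnings(expect_error(fitDcaLogistic(d, "sep"), "separation"))
})

test_that("MD models are location-invariant except for the intercept", {
  sim <- simulateCohort(cohortSimConfig(n_subjects = 200, seed = 21))
  d <- sim$cohort
  f1 <- fitMdLinear(d, "LA_V", "all")
  d$MD <- d$MD + 5
  f2 <- fitMdLinear(d, "LA_V", "all")
  keep <- f1$term != "(Intercept)"
  expect_equal(f1$B[keep], f2$B[keep], tolerance = 1e-10)
  expect_equal(f2$B[!keep] - f1$B[!keep], 5, tolerance = 1e-8)
})

test_that("MD model subsets select the intended eyes", {
  sim <- simulateCohort(cohortSimConfig(n_subjects = 300, seed = 30))
  d <- sim$cohort
  fall <- fitMdLinear(d, "LA_V", "all")
  fnp <- fitMdLinear(d, "LA_V", "nonpm")
  fpm <- fitMdLinear(d, "LA_V", "pm")
  nrel <- sum(d$vf_reliable)
  expect_identical(unique(fall$n), nrel)
  expect_identical(unique(fnp$n) + unique(fpm$n), nrel)
  expect_error(fitMdLinear(d[1:4, ], "LA_V", "all"), "too few")
})
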