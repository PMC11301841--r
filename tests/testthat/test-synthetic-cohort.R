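test_that("a degenerate category simplex labels every eye C1", {
  sim <- simulateCohort(cohortSimConfig(n_subjects = 40,
                                        group_proportions = c(0, 1, 0),
                                        seed = 1))
  expect_true(all(sim$cohort$category == "C1"))
  expect_true(all(!sim$cohort$dca))
})

test_that("zero intra-subject correlation leaves fellow eyes uncorrelated", {
  sim <- simulateCohort(cohortSimConfig(n_subjects = 500,
                                        intra_subject_correlation = 0,
                                        seed = 17))
  d <- sim$cohort
  od <- d$ChT_V[d$eye == "OD"]; os <- d$ChT_V[d$eye == "OS"]
  expect_lt(abs(stats::cor(od, os)), 0.1)
})

test_that("positive correlation shows up between fellow eyes", {
  sim <- simulateCohort(cohortSimConfig(n_subjects = 500,
                                        intra_subject_correlation = 0.8,
                                        seed = 18))
  d <- sim$cohort
  od <- d$ChT_V[d$eye == "OD"]; os <- d$ChT_V[d$eye == "OS"]
  expect_gt(stats::cor(od, os), 0.4)
})

test_that("the emulated category mix is reproduced at scale", {
  sim <- simulateCohort(cohortSimConfig(n_subjects = 2000, seed = 23))
  share <- mean(sim$cohort$category == "C2")
  expect_lt(abs(share - 0.174), 0.02)
})

test_that("identical config and seed reproduce the cohort exactly", {
  cfg <- cohortSimConfig(n_subjects = 80, seed = 31)
  expect_identical(simulateCohort(cfg)$cohort, simulateCohort(cfg)$cohort)
})

test_that("the DCA label matches the category in the default mode", {
  sim <- simulateCohort(cohortSimConfig(n_subjects = 200, seed = 3))
  expect_identical(sim$cohort$dca, sim$cohort$category == "C2")
})

test_that("the logistic mode induces the configured LA association", {
  sim <- simulateCohort(cohortSimConfig(n_subjects = 800,
                                        dcaMode = "logistic", seed = 29))
  d <- sim$cohort
  expect_identical(sim$cohort$dca, sim$cohort$category == "C2")
  # diseased eyes carry smaller luminal areas under the negative link
  expect_lt(mean(d$LA_V[d$dca]), mean(d$LA_V[!d$dca]))
})

test_that("invalid cohort configurations are rejected", {
  expect_error(cohortSimConfig(group_proportions = c(0.5, 0.5, 0.5)),
               "summing to 1")
  expect_error(cohortSimConfig(intra_subject_correlation = 1), "\\[0, 1\\)")
  expect_error(cohortSimConfig(age_sd = c(-1, 1, 1)), "SDs")
})

test_that("generated MD tracks the configured linear link", {
  sim <- simulateCohort(cohortSimConfig(n_subjects = 800, seed = 41))
  d <- sim$cohort
  fit <- stats::lm(MD ~ age + height + AL + corneal_curvature + LA_V,
                   data = d)
  est <- unname(stats::coef(fit)[["LA_V"]])
  se <- sqrt(sandwich::vcovCL(fit, cluster = d$subject_id)["LA_V", "LA_V"])
  expect_lt(abs(est - sim$truth$md_coefs[["LA_V"]]), 3 * se)
})
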