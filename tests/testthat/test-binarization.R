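test_that("a uniform image produces zero lumen pixels (tie rule)", {
  fx <- makeBandImage(stroma = 137, background = 137)
  bin <- niblackBinarize(fx$bscan, fx$boundaries)
  expect_identical(lumenPixels(bin), 0L)
  expect_identical(stromaPixels(bin), sum(bandThicknessPx(fx$boundaries)))
})

test_that("labels partition the band over valid columns", {
  sim <- simulateBScan(imageSimConfig(target_lumen_fraction = 0.45,
                                      seed = 14))
  bin <- niblackBinarize(sim$bscan, sim$truth$boundaries)
  expect_identical(lumenPixels(bin) + stromaPixels(bin),
                   sum(sim$truth$band_mask))
  lab <- choroidLabels(bin)
  expect_identical(lab != 0L, sim$truth$band_mask)
})

test_that("labels are invariant under positive affine intensity rescaling", {
  set.seed(71)
  for (rep in 1:5) {
    m <- matrix(stats::runif(40 * 30, 0, 250), 40, 30)
    b <- ChoroidBoundaries(rep(8L, 30), rep(33L, 30))
    img <- BScan(m, 2, 12, 15L, "vertical")
    a <- stats::runif(1, 0.2, 5); off <- stats::runif(1, 0, 100)
    img2 <- BScan(a * m + off, 2, 12, 15L, "vertical")
    cfg <- binarizationConfig(window_px = 7L, k = -0.2)
    expect_identical(choroidLabels(niblackBinarize(img, b, cfg)),
                     choroidLabels(niblackBinarize(img2, b, cfg)))
  }
})

test_that("thresholds match the brute-force window oracle on a 7x7 image", {
  set.seed(3)
  m <- matrix(sample.int(255L, 49, replace = TRUE), 7, 7)
  storage.mode(m) <- "double"
  expect_equal(niblackThreshold(m, 3L, -0.2), bruteNiblack(m, 3L, -0.2),
               tolerance = 1e-12)
  # and labels agree with direct per-pixel comparison against the oracle
  b <- ChoroidBoundaries(rep(1L, 7), rep(7L, 7))
  img <- BScan(m, 2, 12, 4L, "vertical")
  lab <- choroidLabels(niblackBinarize(img, b, binarizationConfig(3L, -0.2)))
  expect_identical(lab == 2L, m < bruteNiblack(m, 3L, -0.2))
})

test_that("window statistics use population SD and reflective padding", {
  # hand-checkable 3x3 case: center window covers the matrix exactly
  m <- matrix(c(1, 2, 3, 4, 5, 6, 7, 8, 9), 3, 3)
  thr <- niblackThreshold(m, 3L, -0.5)
  mu <- mean(m)
  sig <- sqrt(mean((m - mu)^2))           # population, not sample, SD
  expect_equal(thr[2, 2], mu - 0.5 * sig, tolerance = 1e-12)
})

test_that("invalid configurations and empty bands are rejected", {
  expect_error(binarizationConfig(window_px = 4L), "odd")
  expect_error(binarizationConfig(window_px = 1L), "odd")
  fx <- makeBandImage()
  empty <- ChoroidBoundaries(rep(NA_integer_, 240), rep(NA_integer_, 240))
  expect_error(niblackBinarize(fx$bscan, empty), "empty")
})

test_that("estimated lumen fraction responds monotonically to the truth", {
  est <- vapply(c(0.2, 0.4, 0.6), function(t) {
    sim <- simulateBScan(imageSimConfig(target_lumen_fraction = t, seed = 77))
    bin <- niblackBinarize(sim$bscan, sim$truth$boundaries)
    lumenPixels(bin) / (lumenPixels(bin) + stromaPixels(bin))
  }, numeric(1))
  expect_true(all(diff(est) > 0))
})
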