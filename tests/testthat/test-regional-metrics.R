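test_that("the region grid tiles the 6-mm window with the stated widths", {
  for (mer in c("vertical", "horizontal")) {
    rg <- partitionRegions(mer)
    expect_equal(rg$width_mm, c(1.5, 1, 1, 1, 1.5))
    expect_equal(sum(rg$width_mm), 6)
    expect_equal(rg$a_mm[-1], rg$b_mm[-5])     # contiguous half-open tiles
    expect_equal(rg$normalize, c(1.5, 1, 1, 1, 1.5))
  }
  expect_identical(partitionRegions("vertical")$name,
                   c("I2", "I1", "C", "S1", "S2"))
})

test_that("nasal/temporal labels mirror between OD and OS", {
  od <- partitionRegions("horizontal", "OD")
  os <- partitionRegions("horizontal", "OS")
  expect_identical(od$name, c("N2", "N1", "C", "T1", "T2"))
  expect_identical(os$name, rev(od$name))
  expect_identical(od$a_mm, os$a_mm)           # geometry unchanged
})

test_that("every in-window column lands in exactly one region", {
  # lateral 10 um/px at the identity AL puts column centers exactly on
  # region edges 50 px from the fovea: the half-open rule must not double
  # count them
  fx <- makeBandImage(width = 700L, lateral = 10, foveaCol = 350L)
  bin <- niblackBinarize(fx$bscan, fx$boundaries,
                         binarizationConfig(window_px = 15L))
  met <- computeMetrics(fx$bscan, fx$boundaries, bin, AL = 24.4)
  expect_identical(sum(met$regions$n_cols), met$meridian$n_cols)
  expect_identical(met$meridian$n_cols, 600L)  # 6 mm at 10 um/px
})

test_that("a uniform all-stroma band gives flat thickness and zero CVI", {
  fx <- makeBandImage(bandTop = 41L, bandBottom = 140L, axial = 2)
  bin <- niblackBinarize(fx$bscan, fx$boundaries)   # uniform band => stroma
  suppressWarnings(met <- computeMetrics(fx$bscan, fx$boundaries, bin,
                                         AL = 24.4))
  done <- !is.na(met$regions$ChT_um)
  expect_true(all(abs(met$regions$ChT_um[done] - 200) < 1e-9))
  expect_true(all(met$regions$CVI[done] == 0))
  expect_equal(met$meridian$ChT_um, 200)
  expect_equal(met$meridian$CVI, 0)
})

test_that("half-lumen labels give CVI one half in every region", {
  fx <- makeBandImage(bandTop = 41L, bandBottom = 140L)
  lab <- matrix(0L, 160, 240)
  lab[41:90, ] <- 2L       # upper half of the band lumen
  lab[91:140, ] <- 1L      # lower half stroma
  bin <- makeBinarized(lab)
  suppressWarnings(met <- computeMetrics(fx$bscan, fx$boundaries, bin,
                                         AL = 25))
  done <- !is.na(met$regions$CVI)
  expect_equal(met$regions$CVI[done], rep(0.5, sum(done)))
  expect_equal(met$meridian$CVI, 0.5)
})

test_that("region areas sum exactly to the meridian totals", {
  sim <- simulateBScan(imageSimConfig(target_lumen_fraction = 0.4, seed = 6))
  bin <- niblackBinarize(sim$bscan, sim$truth$boundaries)
  met <- computeMetrics(sim$bscan, sim$truth$boundaries, bin, AL = 26)
  expect_equal(sum(met$regions$LA_mm2), met$meridian$LA_mm2,
               tolerance = 1e-12)
  expect_equal(sum(met$regions$SA_mm2), met$meridian$SA_mm2,
               tolerance = 1e-12)
  expect_equal(met$meridian$TCA_mm2,
               met$meridian$LA_mm2 + met$meridian$SA_mm2)
  # perifoveal normalization only
  expect_equal(met$regions$LA_norm_mm2,
               met$regions$LA_mm2 / met$regions$normalize)
})

test_that("axial-length changes rescale areas but not CVI or thickness", {
  # image narrower than the window at both ALs, so the analyzed column set
  # is fixed and scaling is exact
  fx <- makeBandImage(width = 200L, lateral = 12)
  lab <- matrix(0L, 160, 200)
  lab[41:80, ] <- 2L; lab[81:140, ] <- 1L
  bin <- makeBinarized(lab)
  suppressWarnings({
    m1 <- computeMetrics(fx$bscan, fx$boundaries, bin, AL = 24.4)
    m2 <- computeMetrics(fx$bscan, fx$boundaries, bin, AL = 28)
  })
  ratio <- lateralFactor(28) / lateralFactor(24.4)
  expect_equal(m2$meridian$LA_mm2 / m1$meridian$LA_mm2, ratio)
  expect_equal(m2$meridian$SA_mm2 / m1$meridian$SA_mm2, ratio)
  expect_equal(m2$meridian$CVI, m1$meridian$CVI)
  expect_equal(m2$meridian$ChT_um, m1$meridian$ChT_um)
})

test_that("regions with no valid columns report missing, not zero", {
  fx <- makeBandImage(width = 240L)
  up <- rep(41L, 240); lo <- rep(140L, 240)
  up[1:60] <- NA; lo[1:60] <- NA        # kill the left perifovea columns
  b <- ChoroidBoundaries(up, lo)
  bin <- niblackBinarize(fx$bscan, b, binarizationConfig(window_px = 15L))
  suppressWarnings(met <- computeMetrics(fx$bscan, b, bin, AL = 24.4))
  left <- met$regions[1, ]
  expect_identical(left$n_valid, 0L)
  expect_true(is.na(left$ChT_um) && is.na(left$LA_mm2) && is.na(left$CVI))
})

test_that("the eye summary is consistent and round-trips through CSV", {
  mets <- lapply(c("vertical", "horizontal"), function(mer) {
    sim <- simulateBScan(imageSimConfig(target_lumen_fraction = 0.4,
                                        seed = 19 + (mer == "vertical")),
                         meridian = mer, eyeId = "eyeA")
    bin <- niblackBinarize(sim$bscan, sim$truth$boundaries)
    computeMetrics(sim$bscan, sim$truth$boundaries, bin, AL = 26.5)
  })
  row <- summarizeEye(vertical = mets[[1]], horizontal = mets[[2]])
  # areas over the 6-mm section match mean thickness within 1 percent
  expect_lt(abs(row$LA_V + row$SA_V - row$ChT_V / 1000 * 6),
            0.01 * row$ChT_V / 1000 * 6)
  expect_lt(abs(row$LA_H + row$SA_H - row$ChT_H / 1000 * 6),
            0.01 * row$ChT_H / 1000 * 6)
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(row, path, row.names = FALSE)
  back <- utils::read.csv(path)
  expect_equal(back$LA_N2, row$LA_N2)
  expect_equal(back$CVI_V, row$CVI_V)

  solo <- summarizeEye(vertical = mets[[1]])
  expect_true(is.na(solo$ChT_H) && is.na(solo$LA_N2))
  expect_false(is.na(solo$ChT_V))
})
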