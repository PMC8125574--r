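test_that("profiles rasterize constructed sections exactly", {
  ## rectangular 40 x 10 section: constant height, full extent
  cut <- toyCut(list(rectPoly(-20, 20, 0, 10)), list(rectPoly(-20, 20, -1, 0)))
  prof <- buildProfile(cut)
  expect_true(all(abs(prof@h[!is.na(prof@h)] - 10) < 1e-9))
  expect_equal(diff(prof@uAnterior), 40)
  expect_equal(diff(range(prof@u)), 40, tolerance = 0.5)

  ## two half-discs of radius 10 and 8: peak heights at the centers
  cut2 <- toyCut(list(halfDiscPoly(-15, 10), halfDiscPoly(15, 8)),
                 list(rectPoly(-30, 30, -1, 0)))
  prof2 <- buildProfile(cut2)
  h <- function(u) prof2@h[which.min(abs(prof2@u - u))]
  expect_equal(h(-15), 10, tolerance = 0.05)
  expect_equal(h(15), 8, tolerance = 0.05)
  expect_equal(diff(prof2@uDistal), 60)

  ## degenerate anterior extent raises a profile error
  tiny <- toyCut(list(rectPoly(0, 3, 0, 5)), list(rectPoly(-30, 30, -1, 0)))
  expect_error(buildProfile(tiny), class = "pianoSign_geometry_error")
})

test_that("peak detection separates double peaks, thresholds prominence, and falls back to inflection", {
  u <- seq(-30, 30, by = 0.25)

  ## two Gaussians (sigma 5) at u = -15 and +15, amplitudes 12 and 8
  h2 <- 12 * exp(-(u + 15)^2 / 50) + 8 * exp(-(u - 15)^2 / 50)
  pk <- detectPeaks(makeProfile(u, h2))
  expect_equal(pk@medialKind, "peak")
  expect_equal(pk@lateralU, -15, tolerance = 0.5)
  expect_equal(pk@medialU, 15, tolerance = 0.5)
  expect_equal(pk@lateralH, 12, tolerance = 0.1)
  expect_gt(pk@prominence, 7)

  ## lateral Gaussian plus a medial linear ramp to a plateau: inflection at
  ## the smoothed curvature-sign change, analytically corner + half window
  hRamp <- 12 * exp(-(u + 15)^2 / 50) + 6 * pmin(pmax((u - 5) / 10, 0), 1)
  pkR <- detectPeaks(makeProfile(u, hRamp))
  expect_equal(pkR@medialKind, "inflection")
  expect_equal(pkR@medialU, 15 + 1, tolerance = 0.5)

  ## a medial bump of half the prominence threshold stays single-peak
  hBump <- 3 + 12 * exp(-(u + 15)^2 / 50) + 0.25 * exp(-(u - 15)^2 / 50)
  expect_equal(detectPeaks(makeProfile(u, hBump))@medialKind, "inflection")
  ## ... and one at double the threshold is a definite peak
  hPk <- 3 + 12 * exp(-(u + 15)^2 / 50) + 1.0 * exp(-(u - 15)^2 / 50)
  expect_equal(detectPeaks(makeProfile(u, hPk))@medialKind, "peak")

  ## monotone profile has no lateral maximum: classification error
  expect_error(detectPeaks(makeProfile(u, (u + 30) / 4)),
               class = "pianoSign_geometry_error")
})

test_that("measurements compose the published quantities with their sign conventions", {
  ## anterior interval [-20, 24], distal interval [-30, 30]
  cut <- toyCut(list(rectPoly(-20, 24, 0, 10)), list(rectPoly(-30, 30, -1, 0)))
  prof <- buildProfile(cut)
  u <- prof@u
  hSynth <- 12 * exp(-(u + 10)^2 / 50) + 8 * exp(-(u - 12)^2 / 50)
  pk <- detectPeaks(makeProfile(u, hSynth))
  m <- measureResection(makeProfile(u, hSynth, uDistal = c(-30, 30)), pk, cut,
                        reference = "sTEA")
  expect_equal(m$MpLp, 44)
  expect_equal(m$ML, 60)
  expect_equal(m$MpLp_ML_pct, 100 * 44 / 60, tolerance = 1e-9)
  expect_equal(m$LD, -2)            # anterior midline 2 mm medial of ML midline
  expect_equal(m$LD_ML_pct, 100 * -2 / 60, tolerance = 1e-9)
  expect_equal(m$MedL_LatL, m$MedL / m$LatL, tolerance = 1e-12)
  expect_identical(m$shape, "double_peak")

  ## homogeneity: scaling the cut scales mm fields and preserves ratios
  fm <- symFemur()
  fr <- canonicalFrame(fm$landmarks)
  cutF <- performResection(fm$mesh, fr, steaAxis(fm$landmarks, fr))
  profF <- buildProfile(cutF)
  pkF <- detectPeaks(profF)
  m1 <- measureResection(profF, pkF, cutF)
  cutS <- scaleCutResult(cutF, 1.07)
  profS <- buildProfile(cutS)
  mS <- measureResection(profS, detectPeaks(profS), cutS)
  for (cn in c("MedL_LatL", "MpLp_ML_pct", "LD_ML_pct"))
    expect_equal(mS[[cn]], m1[[cn]], tolerance = 1e-3)
  for (cn in c("ML", "MpLp"))
    expect_equal(mS[[cn]], 1.07 * m1[[cn]], tolerance = 1e-9)
})

test_that("medial-lateral height ratios round half-up to two decimals", {
  expect_identical(medLatRatio(6.7, 8.3), 0.81)
  expect_identical(medLatRatio(3.1, 8.2), 0.38)
  expect_identical(medLatRatio(5, 5), 1)
  expect_identical(medLatRatio(1.115, 2), 0.56)   # half-up, not banker's
  expect_error(medLatRatio(-1, 2), "positive")
  expect_error(medLatRatio(3, 0), "positive")
})
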