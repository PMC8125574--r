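test_that("sTEA follows the epicondylar landmarks with medial orientation", {
  lm <- toyLandmarks()
  fr <- canonicalFrame(lm)
  ax <- steaAxis(lm, fr)
  expect_equal(ax@direction, c(1, 0, 0))

  ## mislabelled (swapped) epicondyles still give a medially oriented axis
  sw <- lm
  sw@points["lat_epicondyle_prominence", ] <- c(40, 0, 0)
  sw@points["med_epicondyle_sulcus", ] <- c(-40, 0, 0)
  frSw <- canonicalFrame(sw)
  expect_gt(sum(steaAxis(sw, frSw)@direction * frSw@xMed), 0)

  ## synthetic femur: sTEA matches the generator's epicondylar ground truth
  fm <- defFemur()
  frF <- canonicalFrame(fm$landmarks)
  axF <- steaAxis(fm$landmarks, frF)
  truthDir <- (fm$truth@steaMed - fm$truth@steaLat)
  truthDir <- truthDir / sqrt(sum(truthDir^2))
  ang <- acos(min(1, abs(sum(axF@direction * truthDir)))) * 180 / pi
  expect_lt(ang, 0.5)
})

test_that("Whiteside's line and its rotation reference are perpendicular in the axial plane", {
  lm <- toyLandmarks()
  fr <- canonicalFrame(lm)
  wsl <- wslAxis(lm, fr)
  expect_equal(wsl@direction, c(0, 1, 0))
  ref <- wslRotationReference(wsl, fr)
  expect_equal(ref@direction, c(1, 0, 0))

  ## tilting Whiteside's line 5 degrees tilts the reference 5 degrees, same sense
  R <- pianoSign:::rotationAbout(c(0, 0, 1), 5)
  lm5 <- lm
  lm5@points["trochlear_groove_deepest", ] <- drop(R %*% c(0, 20, 0))
  lm5@points["intercondylar_notch_highest", ] <- drop(R %*% c(0, -10, 0))
  fr5 <- canonicalFrame(lm5)
  ref5 <- wslRotationReference(wslAxis(lm5, fr5), fr5)
  expect_equal(axialAngleBetween(ref5, ref, fr), 5, tolerance = 1e-9)

  ## perpendicularity of the axial projections
  pr <- function(a) { d <- a@direction; d[3] <- 0; d / sqrt(sum(d^2)) }
  expect_lt(abs(sum(pr(wslAxis(lm5, fr5)) * pr(ref5))), 1e-9)
})

test_that("Kasa circle fit is exact on circles and matches brute force on noisy data", {
  f <- fitCircle2d(rbind(c(0, 1), c(1, 0), c(0, -1)))
  expect_equal(f@center, c(0, 0), tolerance = 1e-12)
  expect_equal(f@radius, 1, tolerance = 1e-12)
  expect_equal(f@residual, 0, tolerance = 1e-12)

  th <- seq(0, 2 * pi, length.out = 101)[-101]
  pts <- cbind(3 + 21 * cos(th), -2 + 21 * sin(th))
  f2 <- fitCircle2d(pts)
  expect_equal(f2@center, c(3, -2), tolerance = 1e-9)
  expect_equal(f2@radius, 21, tolerance = 1e-9)

  expect_error(fitCircle2d(cbind(1:10, 2 * (1:10) + 3)),
               class = "pianoSign_geometry_error")

  ## Monte-Carlo: noisy circles recover the center within 0.05
  errs <- vapply(1:50, function(s) {
    set.seed(s)
    p <- cbind(5 + 8 * cos(th), -1 + 8 * sin(th)) + matrix(rnorm(200, 0, 0.1), ncol = 2)
    sqrt(sum((fitCircle2d(p)@center - c(5, -1))^2))
  }, numeric(1))
  expect_lt(max(errs), 0.05)

  ## brute-force grid search over (center, radius) agrees to grid resolution
  set.seed(99)
  th12 <- seq(0.2, 2 * pi, length.out = 12)
  noisy <- cbind(cos(th12), sin(th12)) * 4 + matrix(rnorm(24, 0, 0.05), ncol = 2)
  grid <- seq(-0.5, 0.5, by = 0.025)
  best <- c(Inf, NA, NA)
  for (cx in grid) for (cy in grid) {
    rho <- sqrt((noisy[, 1] - cx)^2 + (noisy[, 2] - cy)^2)
    loss <- sum((rho - mean(rho))^2)
    if (loss < best[1]) best <- c(loss, cx, cy)
  }
  fk <- fitCircle2d(noisy)
  expect_lt(max(abs(fk@center - best[2:3])), 0.05)
})

test_that("FEA and PCA recover the symmetric construction and react to asymmetry", {
  fm <- symFemur()
  fr <- canonicalFrame(fm$landmarks)
  stea <- steaAxis(fm$landmarks, fr)
  fea <- feaAxis(fm$mesh, fr)
  pca <- pcaAxis(fm$mesh, fr)
  wref <- wslRotationReference(wslAxis(fm$landmarks, fr), fr)
  for (ax in list(fea, pca, wref))
    expect_lt(abs(axialAngleBetween(ax, stea, fr)), 1)

  ## FEA endpoints match the condylar sphere centers
  ctr <- attr(fea, "centers")
  expect_lt(sqrt(sum((ctr$med - fm$truth@feaMed)^2)), 1)
  expect_lt(sqrt(sum((ctr$lat - fm$truth@feaLat)^2)), 1)

  ## posteriorly deflated lateral condyle rotates the PCA internally
  pDef <- femurParams(rCondMed = 21, rCondLat = 18, hAntMed = 6.7, hAntLat = 6.7,
                      archetype = "deflated", seed = 2)
  fmD <- buildFemur(pDef, pitch = 1.0, pose = "none")
  frD <- canonicalFrame(fmD$landmarks)
  angle <- axialAngleBetween(pcaAxis(fmD$mesh, frD), steaAxis(fmD$landmarks, frD), frD)
  expect_lt(angle, -0.5)
})

test_that("axes are rigid-invariant in frame-relative terms", {
  fm <- defFemur()
  fr0 <- canonicalFrame(fm$landmarks)
  fea0 <- attr(feaAxis(fm$mesh, fr0), "centers")
  set.seed(21)
  R <- pianoSign:::rotationAbout(rnorm(3), runif(1, 10, 170))
  tr <- applyRigid(fm$mesh, fm$landmarks, R, runif(3, -40, 40))
  fr1 <- canonicalFrame(tr$landmarks)
  fea1 <- attr(feaAxis(tr$mesh, fr1), "centers")
  expect_lt(max(abs(frameCoords(fea1$med, fr1) - frameCoords(fea0$med, fr0))), 0.1)
  expect_lt(max(abs(frameCoords(fea1$lat, fr1) - frameCoords(fea0$lat, fr0))), 0.1)
})

test_that("signed axial angles are antisymmetric with the external-positive convention", {
  lm <- toyLandmarks()
  fr <- canonicalFrame(lm)
  a <- new("RotationAxis", point = c(0, 0, 0), direction = c(1, 0, 0), kind = "other")
  expect_equal(axialAngleBetween(a, a, fr), 0)
  d3 <- c(cos(pi / 60), sin(pi / 60), 0)   # 3 degrees externally rotated
  b <- new("RotationAxis", point = c(0, 0, 0), direction = d3, kind = "other")
  expect_equal(axialAngleBetween(b, a, fr), 3, tolerance = 1e-9)
  expect_equal(axialAngleBetween(a, b, fr), -3, tolerance = 1e-9)
})
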