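test_that("distal cut plane sits at the resection depth above the most distal vertex", {
  ## box mesh spanning z in [0, 50]
  box <- unitCubeMesh()
  boxV <- meshVertices(box); boxV[, 3L] <- boxV[, 3L] * 50
  box50 <- TriMesh(boxV, meshFaces(box))
  fr <- canonicalFrame(toyLandmarks())
  pl <- distalCutPlane(box50, fr, depthMm = 9)
  expect_equal(attr(pl, "level"), 9)
  expect_equal(attr(distalCutPlane(box50, fr, depthMm = 0), "level"), 0)
  expect_error(distalCutPlane(box50, fr, depthMm = 60),
               class = "pianoSign_geometry_error")

  ## frame-relative level is rigid-invariant
  fm <- defFemur()
  fr0 <- canonicalFrame(fm$landmarks)
  l0 <- attr(distalCutPlane(fm$mesh, fr0), "level")
  set.seed(31)
  tr <- applyRigid(fm$mesh, fm$landmarks,
                   pianoSign:::rotationAbout(rnorm(3), 77), c(5, -20, 12))
  l1 <- attr(distalCutPlane(tr$mesh, canonicalFrame(tr$landmarks)), "level")
  expect_equal(l1, l0, tolerance = 1e-6)
})

test_that("component frame encodes flexion and rotation exactly", {
  fr <- canonicalFrame(toyLandmarks())
  ref <- new("RotationAxis", point = c(0, 0, 0), direction = c(1, 0, 0), kind = "sTEA")
  cf0 <- componentFrame(fr, ref, flexionDeg = 0)
  expect_equal(cf0@yFlange, c(0, 1, 0), tolerance = 1e-12)

  cf3 <- componentFrame(fr, ref, flexionDeg = 3)
  expect_equal(sum(cf3@zFlex * fr@zMech), cos(pi * 3 / 180), tolerance = 1e-12)

  ## two references differing by an axial angle differ by that angle in xComp
  d <- c(cos(0.04), sin(0.04), 0)
  ref2 <- new("RotationAxis", point = c(0, 0, 0), direction = d, kind = "WSL")
  cfA <- componentFrame(fr, ref, flexionDeg = 3)
  cfB <- componentFrame(fr, ref2, flexionDeg = 3)
  expect_equal(acos(sum(cfA@xComp * cfB@xComp)), 0.04, tolerance = 1e-9)

  up <- new("RotationAxis", point = c(0, 0, 0), direction = c(0, 0, 1), kind = "other")
  expect_error(componentFrame(fr, up), class = "pianoSign_geometry_error")
})

test_that("anterior plane is tangent to the cortex and reacts monotonically to the band", {
  fm <- defFemur()
  fr <- canonicalFrame(fm$landmarks)
  cf <- componentFrame(fr, steaAxis(fm$landmarks, fr))
  level <- attr(distalCutPlane(fm$mesh, fr), "level")
  pl <- anteriorCutPlane(fm$mesh, cf, fr, level, bandMm = c(25, 45))
  V <- meshVertices(fm$mesh)
  z <- frameCoords(V, fr)[, 3L]
  inBand <- z >= level + 25 & z <= level + 45
  expect_lte(max(pianoSign:::planeDistance(V[inBand, ], pl)), 1e-6)

  ## raising the band moves the plane posteriorly or not at all
  pl2 <- anteriorCutPlane(fm$mesh, cf, fr, level, bandMm = c(35, 45))
  expect_lte(sum((pl2@point - pl@point) * cf@yFlange), 1e-9)

  ## flexion 0 vs 3 degrees differ by exactly that dihedral angle
  cf0 <- componentFrame(fr, steaAxis(fm$landmarks, fr), flexionDeg = 0)
  pl0 <- anteriorCutPlane(fm$mesh, cf0, fr, level, bandMm = c(25, 45))
  expect_equal(acos(sum(pl0@normal * pl@normal)) * 180 / pi, 3, tolerance = 1e-9)
})

test_that("cross-sections match closed-form areas and report empty planes", {
  cube <- unitCubeMesh()
  mid <- pianoSign:::makePlane(c(0.5, 0.5, 0.5), c(0, 0, 1))
  sec <- crossSection(cube, mid)
  expect_length(sec, 1L)
  expect_equal(abs(polygonArea(sec[[1L]])), 1, tolerance = 1e-9)

  sph <- sphereMesh(10, 0.25)
  off <- pianoSign:::makePlane(c(0, 0, 6), c(0, 0, 1))
  sec2 <- crossSection(sph, off)
  expect_length(sec2, 1L)
  expect_equal(abs(polygonArea(sec2[[1L]])), pi * 64, tolerance = pi * 64 * 0.01)

  miss <- pianoSign:::makePlane(c(0, 0, 20), c(0, 0, 1))
  expect_error(crossSection(sph, miss), class = "pianoSign_geometry_error")
})

test_that("full resection has the documented structure and parameter round-trip", {
  fm <- symFemur()
  fr <- canonicalFrame(fm$landmarks)
  cfg <- defaultConfig()
  cfg$resection$extraRotationDeg <- 2.5
  cut <- performResection(fm$mesh, fr, steaAxis(fm$landmarks, fr), cfg)
  cf <- attr(cut, "componentFrame")

  ## distal cutting line direction is perpendicular to both plane normals
  lineDir3d <- cut@anteriorPlane@uDir
  expect_lt(abs(sum(lineDir3d * cut@anteriorPlane@normal)), 1e-9)
  expect_lt(abs(sum(lineDir3d * fr@zMech)), 1e-9)

  ## flexion and extra rotation are recoverable from the emitted planes
  expect_equal(acos(sum(cut@anteriorPlane@vDir * fr@zMech)) * 180 / pi,
               cfg$resection$flexionDeg, tolerance = 1e-9)
  axComp <- new("RotationAxis", point = fr@origin, direction = cf@xComp, kind = "other")
  expect_equal(axialAngleBetween(axComp, steaAxis(fm$landmarks, fr), fr), 2.5,
               tolerance = 1e-9)

  ## mirror symmetry of the anterior section (no extra rotation): the two
  ## u half-areas agree
  cut0 <- performResection(fm$mesh, fr, steaAxis(fm$landmarks, fr), defaultConfig())
  halfArea <- function(sign) {
    sum(vapply(cut0@anteriorSection, function(p) {
      cl <- pianoSign:::clipAboveV(cbind(p[, 2L], sign * p[, 1L]), 0)
      if (is.null(cl)) 0 else abs(polygonArea(cl))
    }, numeric(1)))
  }
  aLat <- halfArea(-1); aMed <- halfArea(1)
  expect_lt(abs(aLat / aMed - 1), 0.03)

  ## rotation references differing by > 1 degree change the anterior section
  ## (checked on an asymmetric femur, where the area is not stationary)
  fmA <- defFemur()
  frA <- canonicalFrame(fmA$landmarks)
  cfgRot <- defaultConfig(); cfgRot$resection$extraRotationDeg <- 3
  cutA0 <- performResection(fmA$mesh, frA, steaAxis(fmA$landmarks, frA), defaultConfig())
  cutA1 <- performResection(fmA$mesh, frA, steaAxis(fmA$landmarks, frA), cfgRot)
  aA0 <- sum(vapply(cutA0@anteriorSection, function(p) abs(polygonArea(p)), numeric(1)))
  aA1 <- sum(vapply(cutA1@anteriorSection, function(p) abs(polygonArea(p)), numeric(1)))
  expect_gt(abs(aA1 - aA0), 1)

  ## uniform scaling of the cut result scales areas quadratically
  a0 <- sum(vapply(cut0@anteriorSection, function(p) abs(polygonArea(p)), numeric(1)))
  sc <- scaleCutResult(cut0, 2)
  aS <- sum(vapply(sc@anteriorSection, function(p) abs(polygonArea(p)), numeric(1)))
  expect_equal(aS, 4 * a0, tolerance = 1e-12)
})
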