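test_that("canonical frame has the documented axes and orthonormality", {
  fr <- canonicalFrame(toyLandmarks())
  expect_equal(fr@zMech, c(0, 0, 1))
  expect_equal(fr@xMed, c(1, 0, 0))
  expect_equal(fr@yAnt, c(0, 1, 0))
  expect_equal(fr@handedness, 1)
  expect_lt(abs(sum(fr@xMed * fr@zMech)), 1e-9)

  ## epicondylar segment tilted proximally still yields x perpendicular to z
  lm <- toyLandmarks()
  lm@points["med_epicondyle_sulcus", ] <- c(40, 0, 8)
  fr2 <- canonicalFrame(lm)
  expect_lt(abs(sum(fr2@xMed * fr2@zMech)), 1e-9)
  expect_equal(det(cbind(fr2@xMed, fr2@yAnt, fr2@zMech)), 1, tolerance = 1e-9)
})

test_that("degenerate landmark configurations raise geometry errors", {
  lm <- toyLandmarks()
  lm@points["med_epicondyle_sulcus", ] <- c(0, 0, 100)
  lm@points["lat_epicondyle_prominence", ] <- c(0, 0, -100)
  expect_error(canonicalFrame(lm), class = "pianoSign_geometry_error")
})

test_that("left knees canonicalize onto the right-knee convention", {
  fm <- defFemur()
  mir <- mirrorWorld(fm$mesh, fm$landmarks)
  expect_equal(kneeSide(mir$landmarks), "left")
  canR <- toCanonical(fm$mesh, fm$landmarks)
  canL <- toCanonical(mir$mesh, mir$landmarks)
  expect_equal(canL$landmarks@points, canR$landmarks@points, tolerance = 1e-9)
  expect_equal(meshVertices(canL$mesh), meshVertices(canR$mesh), tolerance = 1e-9)
  expect_equal(canL$frame@handedness, -1)
  ## normalizing a right knee already in canonical pose is the identity
  expect_equal(meshVertices(canR$mesh), meshVertices(fm$mesh), tolerance = 1e-9)
})

test_that("rigid transforms behave as isometries and reject reflections", {
  fm <- defFemur()
  idt <- applyRigid(fm$mesh, fm$landmarks)
  expect_identical(meshVertices(idt$mesh), meshVertices(fm$mesh))

  tr <- applyRigid(fm$mesh, fm$landmarks, t = c(10, 0, 0))
  expect_equal(meshVertices(tr$mesh)[, 1L], meshVertices(fm$mesh)[, 1L] + 10)

  set.seed(11)
  R <- pianoSign:::rotationAbout(rnorm(3), runif(1, 0, 180))
  rt <- applyRigid(fm$mesh, fm$landmarks, R, runif(3, -50, 50))
  d0 <- dist(fm$landmarks@points)
  d1 <- dist(rt$landmarks@points)
  expect_equal(as.numeric(d1), as.numeric(d0), tolerance = 1e-9)
  ## frame-relative landmark coordinates are invariant under rigid motion
  c0 <- frameCoords(fm$landmarks@points, canonicalFrame(fm$landmarks))
  c1 <- frameCoords(rt$landmarks@points, canonicalFrame(rt$landmarks))
  expect_equal(c1, c0, tolerance = 1e-6)

  M <- diag(c(-1, 1, 1))
  expect_error(applyRigid(fm$mesh, fm$landmarks, M), "proper rotation")
})
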