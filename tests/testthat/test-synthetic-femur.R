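test_that("parameter sampling is deterministic and archetypes are calibrated", {
  a <- sampleFemurParams("female-like", seed = 42)
  b <- sampleFemurParams("female-like", seed = 42)
  expect_equal(a@mlWidth, b@mlWidth)
  expect_identical(a@noiseBasis, b@noiseBasis)
  expect_identical(a@side, b@side)

  expect_error(sampleFemurParams("canine", seed = 1), "archetype")

  p0 <- sampleFemurParams("male-like", seed = 7, noiseAmplitude = 0)
  expect_identical(p0@noiseAmplitude, 0)

  ## law of large numbers on the configured ML width means
  for (arch in c("female-like", "male-like")) {
    w <- vapply(seq_len(1000), function(s)
      sampleFemurParams(arch, seed = s)@mlWidth, numeric(1))
    target <- if (arch == "female-like") 73 else 84
    expect_lt(abs(mean(w) - target), 1)
  }
  ## female-like archetype has the larger medial-to-lateral facet ratio
  rat <- function(arch) mean(vapply(1:200, function(s) {
    p <- sampleFemurParams(arch, seed = s); p@hAntMed / p@hAntLat
  }, numeric(1)))
  expect_gt(rat("female-like"), rat("male-like"))
})

test_that("implicit field has the right signs and a single surface crossing", {
  p <- femurParams(seed = 5)
  cc <- pianoSign:::condyleCenters(p)
  expect_lt(implicitValue(p, cc$med), 0)
  expect_lt(implicitValue(p, cc$lat), 0)
  expect_gt(implicitValue(p, c(10 * p@mlWidth, 0, 0)), 0)

  ## sign flips exactly once along rays from the medial condyle center
  set.seed(3)
  for (i in 1:6) {
    dir <- rnorm(3); dir <- dir / sqrt(sum(dir^2))
    t <- seq(0, 120, by = 0.05)
    f <- implicitValue(p, outer(t, dir) + rep(cc$med, each = length(t)))
    expect_equal(sum(diff(sign(f)) != 0), 1L)
  }
})

test_that("built femurs are watertight with calibrated extent and landmarks on the surface", {
  fm <- defFemur()
  expect_true(meshIsClosed(fm$mesh))
  V <- meshVertices(fm$mesh)
  p <- fm$truth@params
  expect_lt(abs(diff(range(V[, 1L])) - p@mlWidth), 0.8)

  ## bony landmarks lie within one voxel of the surface (clean geometry)
  for (nm in c("lat_epicondyle_prominence", "med_epicondyle_sulcus",
               "trochlear_groove_deepest", "intercondylar_notch_highest")) {
    lm <- landmark(fm$landmarks, nm)
    expect_lt(sqrt(min(rowSums(sweep(V, 2L, lm)^2))), 0.8)
  }
})

test_that("symmetric parameters give a mirror-symmetric femur", {
  p <- symmetricFemurParams(1)
  set.seed(8)
  q <- cbind(runif(500, -40, 40), runif(500, -35, 25), runif(500, -25, 45))
  qm <- q; qm[, 1L] <- -qm[, 1L]
  expect_equal(implicitValue(p, q), implicitValue(p, qm), tolerance = 1e-12)

  ## mesh vertices map onto the surface under mirroring (field is symmetric
  ## and near zero at vertices)
  fm <- symFemur()
  V <- meshVertices(fm$mesh)
  fv <- abs(implicitValue(p, cbind(-V[, 1L], V[, 2L], V[, 3L])))
  expect_lt(stats::quantile(fv, 0.999), 0.4)
})

test_that("cohort generation on disk is reproducible and complete", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  m1 <- generateCohort(2, 2, seed = 5, outDir = d1, pitch = 1.8, noiseAmplitude = 0.3)
  m2 <- generateCohort(2, 2, seed = 5, outDir = d2, pitch = 1.8, noiseAmplitude = 0.3)
  expect_equal(nrow(m1), 4L)
  expect_equal(m1$sex, c("female", "female", "male", "male"))
  for (i in seq_len(4L)) {
    expect_identical(unname(tools::md5sum(m1$truth[i])), unname(tools::md5sum(m2$truth[i])))
    expect_identical(unname(tools::md5sum(m1$landmarks[i])), unname(tools::md5sum(m2$landmarks[i])))
    expect_identical(unname(tools::md5sum(m1$mesh[i])), unname(tools::md5sum(m2$mesh[i])))
  }
  ## distinct per-knee seeds give distinct meshes
  expect_gt(length(unique(tools::md5sum(m1$mesh))), 1L)
  expect_error(generateCohort(0, 2, seed = 1, outDir = d1), "sizes")

  ## ground truth round-trips through JSON
  tr <- loadTruth(m1$truth[1])
  expect_s4_class(tr, "FemurTruth")
  expect_equal(tr@params@seed, m1$seed[1])
  fm <- buildFemur(tr@params, pitch = 1.8, pose = "random")
  expect_equal(fm$truth@feaMed, tr@feaMed, tolerance = 1e-8)
})
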