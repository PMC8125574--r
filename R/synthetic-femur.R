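# Parametric synthetic distal femur with analytic ground truth.
#
# The bone is an implicit solid (negative inside): a smooth union of a shaft
# frustum, two condylar spheres (whose sagittal great circles are the true
# flexion-extension circle profiles) and two anterior facet prisms, minus a
# trochlear V-groove wedge and an intercondylar notch, plus band-limited
# smooth surface noise. The mesh is the zero level set polygonized by
# marching tetrahedra; landmarks and axis ground truth are placed
# analytically from the parameters, so every downstream stage can be tested
# against known truth.
#
# Canonical build pose: knee center at the origin, +x medial, +y anterior,
# +z proximal. Left-sided femurs are mirrored about x = 0 and a random rigid
# pose can be applied afterwards; both are recorded in the ground truth.

GROOVE_DATUM_Z <- -14      # distal datum for the groove floor line, mm
GROOVE_RUN_MM <- 20        # groove reaches its nominal depth this far proximal of the datum
FACET_TAPER_Z0 <- -10      # facet fronts start receding proximal of this level
CORTEX_APEX_Z <- 24        # z of the anterior cortical bow apex, mm
CONDYLE_SETBACK <- 3       # condylar sphere fronts sit this far behind the cortex line, mm
BLEND_UNION <- 1.2         # smooth-union blend radius, mm
BLEND_CARVE <- 0.8         # blend radius of the groove/notch subtraction, mm

## stable soft-min of the columns of a matrix (exponential smoothing)
sminK <- function(F, k) {
  m <- do.call(pmin, as.data.frame(F))
  s <- rowSums(exp(-(F - m) / k))
  m - k * log(s)
}

smaxPair <- function(a, b, k) -sminK(cbind(-a, -b), k)

condyleCenters <- function(params) {
  W <- params@mlWidth
  rMax <- max(params@rCondMed, params@rCondLat)
  yCond <- params@shaftRadius - CONDYLE_SETBACK - rMax
  list(med = c(W / 2 - params@rCondMed, yCond, 0),
       lat = c(-(W / 2 - params@rCondLat), yCond, 0))
}

#' Signed implicit field of a synthetic femur
#'
#' Negative inside the bone, positive outside, approximately a signed
#' distance in mm away from blend regions. Evaluated in the femur's
#' canonical build coordinates (before any mirroring or pose).
#'
#' @param params a \linkS4class{FemurParams}.
#' @param points n x 3 matrix (or length-3 vector) of query points, mm.
#' @return Numeric vector of field values.
#' @export
implicitValue <- function(params, points) {
  p <- if (is.null(dim(points))) matrix(points, 1L) else as.matrix(points)
  x <- p[, 1L]; y <- p[, 2L]; z <- p[, 3L]
  W <- params@mlWidth
  cc <- condyleCenters(params)

  ## shaft with a convex anterior cortical bow (apex at CORTEX_APEX_Z), so a
  ## 3-degree-flexed tangent plane touches the cortex once and stays clear of
  ## it elsewhere; capped at z in [-18, 42]
  rShaft <- params@shaftRadius -
    0.0015 * params@shaftTaper * (z - CORTEX_APEX_Z)^2
  fShaft <- pmax(sqrt(x^2 + y^2) - rShaft, -18 - z, z - 42)

  fMed <- sqrt((x - cc$med[1L])^2 + (y - cc$med[2L])^2 + (z - cc$med[3L])^2) - params@rCondMed
  fLat <- sqrt((x - cc$lat[1L])^2 + (y - cc$lat[2L])^2 + (z - cc$lat[3L])^2) - params@rCondLat

  ## anterior facet shelf: rounded boxes meeting at the midline (the V-groove
  ## is carved out of the shelf below); fronts recede proximally
  facet <- function(xLo, xHi, h) {
    yHi <- params@shaftRadius + h - params@facetTaperSlope * pmax(z - FACET_TAPER_Z0, 0)
    q1 <- pmax(xLo - x, x - xHi)
    q2 <- pmax(-8 - y, y - yHi)
    q3 <- pmax(-14 - z, z - 18)
    rnd <- 1.5
    inside <- pmin(pmax(q1, q2, q3), 0)
    sqrt(pmax(q1 + rnd, 0)^2 + pmax(q2 + rnd, 0)^2 + pmax(q3 + rnd, 0)^2) - rnd + inside
  }
  fFacMed <- facet(0, W / 2 - 11, params@hAntMed)
  fFacLat <- facet(-(W / 2 - 11), 0, params@hAntLat)

  ## condyles and facets blend smoothly; the shaft joins crisply so the
  ## anterior cortex is exactly the bowed cylinder (the flange plane must be
  ## tangent to it, with no blend bulge piercing the plane below the band)
  f <- pmin(fShaft, sminK(cbind(fMed, fLat, fFacMed, fFacLat), BLEND_UNION))

  ## trochlear V-groove: wedge opening anteriorly, apex on the groove floor line
  mG <- 1 / tan(deg2rad(params@grooveApexAngle / 2))
  gApex <- params@shaftRadius - (params@grooveDepth / GROOVE_RUN_MM) * (z - GROOVE_DATUM_Z)
  g <- pmax(gApex + mG * abs(x) - y, -26 - z, z - 6)
  f <- smaxPair(f, -g, BLEND_CARVE)

  ## intercondylar notch: distal-posterior slab between the condyles
  nb <- pmax(abs(x) - 6, y - 8, z + 10)
  f <- smaxPair(f, -nb, BLEND_CARVE)

  if (params@noiseAmplitude > 0 && nrow(params@noiseBasis) > 0) {
    B <- params@noiseBasis
    noise <- numeric(length(x))
    for (i in seq_len(nrow(B)))
      noise <- noise + B[i, 5L] * sin(B[i, 4L] * (B[i, 1L] * x + B[i, 2L] * y + B[i, 3L] * z) + B[i, 6L])
    f <- f + params@noiseAmplitude * noise
  }
  f
}

## Sum of nWaves random-direction sinusoids with wavelengths in
## [wavelength, wavelength + 4] mm and amplitudes summing to 1, so the
## noise field is bounded by +-1 and noiseAmplitude is the maximum surface
## displacement of the undulation.
makeNoiseBasis <- function(wavelength, nWaves = 6L) {
  dir <- matrix(stats::rnorm(nWaves * 3L), nWaves)
  dir <- dir / sqrt(rowSums(dir^2))
  lambda <- stats::runif(nWaves, wavelength, wavelength + 4)
  cbind(dir, 2 * pi / lambda, rep(1 / nWaves, nWaves),
        stats::runif(nWaves, 0, 2 * pi))
}

#' Construct femur generator parameters explicitly
#'
#' Defaults correspond to the female-like archetype means. The overall
#' anteroposterior depth is derived from the condylar radii, shaft radius
#' and lateral facet height (the condylar sphere fronts sit a fixed setback
#' behind the cortex line) and recorded in the \code{apDepth} slot. The
#' sinusoidal noise basis is drawn from \code{seed} and frozen into the
#' object, so the implicit field is a pure function of the returned
#' parameters.
#'
#' @param mlWidth,rCondMed,rCondLat,shaftRadius,shaftTaper,grooveDepth,grooveApexAngle,hAntMed,hAntLat,facetTaperSlope,epiOffMed,epiOffLat,noiseAmplitude,noiseWavelength
#'   geometry parameters, mm and degrees; see \linkS4class{FemurParams}.
#' @param side "left" or "right".
#' @param archetype free label recorded in the object.
#' @param seed integer seed for the noise basis.
#' @return A \linkS4class{FemurParams}.
#' @export
femurParams <- function(mlWidth = 73, rCondMed = 20.5, rCondLat = 21.5,
                        shaftRadius = 14.5, shaftTaper = 2, grooveDepth = 5,
                        grooveApexAngle = 125, hAntMed = 6.1, hAntLat = 6.7,
                        facetTaperSlope = 0.55, epiOffMed = c(0, 0), epiOffLat = c(0, 0),
                        noiseAmplitude = 0, noiseWavelength = 12,
                        side = "right", archetype = "custom", seed = 1L) {
  basis <- withSeed(seed + 777L, makeNoiseBasis(noiseWavelength))
  apDepth <- hAntLat + CONDYLE_SETBACK + 2 * max(rCondMed, rCondLat)
  new("FemurParams", mlWidth = mlWidth, apDepth = apDepth, rCondMed = rCondMed,
      rCondLat = rCondLat, shaftRadius = shaftRadius, shaftTaper = shaftTaper,
      grooveDepth = grooveDepth, grooveApexAngle = grooveApexAngle,
      hAntMed = hAntMed, hAntLat = hAntLat, facetTaperSlope = facetTaperSlope,
      epiOffMed = epiOffMed, epiOffLat = epiOffLat,
      noiseAmplitude = noiseAmplitude, noiseWavelength = noiseWavelength,
      noiseBasis = basis, side = side, archetype = archetype, seed = as.numeric(seed))
}

#' Modify femur parameters
#'
#' Returns a copy with the named slots replaced (used e.g. to plant a
#' configured effect on a sampled cohort member); the result is revalidated.
#'
#' @param params a \linkS4class{FemurParams}.
#' @param ... named slot replacements.
#' @return A \linkS4class{FemurParams}.
#' @export
modifyFemurParams <- function(params, ...) {
  mods <- list(...)
  for (nm in names(mods)) slot(params, nm) <- mods[[nm]]
  validObject(params)
  params
}

## Archetype distributions. Means echo published sex contrasts in distal
## femoral anatomy (mediolateral widths; anterior condylar heights for the
## facet means); they are documented stand-ins, not population claims.
ARCHETYPES <- list(
  "female-like" = list(
    mlWidth = c(73, 3.1, 60, 98),
    rCondMed = c(20.5, 1.0, 16, 30), rCondLat = c(21.5, 1.0, 16, 30),
    shaftRadius = c(14.5, 0.8, 12, 19), hAntMed = c(6.1, 0.6, 1.0, 11),
    hAntLat = c(6.7, 0.7, 1.5, 11)),
  "male-like" = list(
    mlWidth = c(84, 4.2, 60, 98),
    rCondMed = c(23.5, 1.2, 16, 30), rCondLat = c(24.5, 1.2, 16, 30),
    shaftRadius = c(16, 0.9, 12, 19), hAntMed = c(6.7, 0.7, 1.0, 11),
    hAntLat = c(8.3, 0.8, 1.5, 11))
)

#' Draw femur parameters for a sex archetype
#'
#' Parameters are drawn from documented truncated-normal distributions; the
#' two archetypes differ in mediolateral width, anteroposterior depth,
#' condylar radii and anterior facet heights (the female-like archetype has
#' the larger medial-to-lateral facet height ratio). Identical seeds give
#' identical parameters.
#'
#' @param archetype "female-like" or "male-like".
#' @param seed integer seed.
#' @param side "left", "right", or NULL to draw at random.
#' @param noiseAmplitude surface noise RMS amplitude, mm.
#' @return A \linkS4class{FemurParams}.
#' @export
sampleFemurParams <- function(archetype, seed, side = NULL, noiseAmplitude = 0.4) {
  if (!archetype %in% names(ARCHETYPES))
    stop("unknown archetype: ", archetype, " (use 'female-like' or 'male-like')",
         call. = FALSE)
  a <- ARCHETYPES[[archetype]]
  withSeed(seed, {
    draw <- function(spec) rtruncnorm1(1L, spec[1L], spec[2L], spec[3L], spec[4L])
    vals <- lapply(a, draw)
    if (is.null(side)) side <- sample(c("left", "right"), 1L)
    femurParams(mlWidth = vals$mlWidth,
                rCondMed = vals$rCondMed, rCondLat = vals$rCondLat,
                shaftRadius = vals$shaftRadius,
                shaftTaper = rtruncnorm1(1L, 2, 0.3, 1, 3),
                grooveDepth = rtruncnorm1(1L, 5, 0.5, 3.5, 6.5),
                grooveApexAngle = rtruncnorm1(1L, 125, 5, 110, 140),
                hAntMed = vals$hAntMed, hAntLat = vals$hAntLat,
                facetTaperSlope = rtruncnorm1(1L, 0.55, 0.04, 0.45, 0.7),
                epiOffMed = rtruncnorm1(2L, 0, 1.5, -4, 4),
                epiOffLat = rtruncnorm1(2L, 0, 1.5, -4, 4),
                noiseAmplitude = noiseAmplitude,
                noiseWavelength = stats::runif(1L, 8, 10),
                side = side, archetype = archetype, seed = seed)
  })
}

#' Mirror-symmetric femur parameters
#'
#' Every mediolaterally paired field is equal and the surface noise is off,
#' so the built femur is mirror-symmetric about the sagittal plane; used by
#' the symmetry property checks (MedL/LatL = 1, LD = 0).
#'
#' @param seed integer seed (noise basis only; noise amplitude is 0).
#' @return A \linkS4class{FemurParams}.
#' @export
symmetricFemurParams <- function(seed = 1L) {
  femurParams(rCondMed = 21, rCondLat = 21, hAntMed = 6.7, hAntLat = 6.7,
              epiOffMed = c(0, 0), epiOffLat = c(0, 0), noiseAmplitude = 0,
              archetype = "symmetric", seed = seed)
}

analyticLandmarks <- function(params) {
  cc <- condyleCenters(params)
  epiDir <- function(sgn, off) {
    normalize(c(sgn, tan(deg2rad(off[1L])), tan(deg2rad(off[2L]))))
  }
  med <- cc$med + params@rCondMed * epiDir(1, params@epiOffMed)
  lat <- cc$lat + params@rCondLat * epiDir(-1, params@epiOffLat)
  groove <- c(0, params@shaftRadius -
                (params@grooveDepth / GROOVE_RUN_MM) * (-8 - GROOVE_DATUM_Z), -8)
  notch <- c(0, 0, -10)
  LandmarkSet(list(lat_epicondyle_prominence = lat, med_epicondyle_sulcus = med,
                   trochlear_groove_deepest = groove,
                   intercondylar_notch_highest = notch,
                   femoral_head_center = c(0, 0, 400), knee_center = c(0, 0, 0)),
              side = "right")
}

#' Build a synthetic femur mesh with landmarks and ground truth
#'
#' Polygonizes the implicit field by marching tetrahedra at the given voxel
#' pitch, places the landmarks analytically, optionally mirrors the femur
#' for a left side and applies a random rigid pose (drawn from the parameter
#' seed). The ground truth records the true flexion-extension circle centers
#' (the condylar sphere centers), the epicondylar points, and the pose.
#'
#' @param params a \linkS4class{FemurParams}.
#' @param pitch marching grid voxel pitch, mm (fidelity knob; default 0.8).
#' @param pose "random" applies a seed-derived rigid pose, "none" keeps the
#'   canonical build pose.
#' @return \code{list(mesh, landmarks, truth)} with \code{truth} a
#'   \linkS4class{FemurTruth}.
#' @export
buildFemur <- function(params, pitch = 0.8, pose = c("random", "none")) {
  pose <- match.arg(pose)
  validObject(params)
  W <- params@mlWidth
  rMax <- max(params@rCondMed, params@rCondLat)
  cc <- condyleCenters(params)
  margin <- 4 + 2 * params@noiseAmplitude
  gx <- seq(-(W / 2 + margin), W / 2 + margin, by = pitch)
  gy <- seq(cc$med[2L] - rMax - margin,
            params@shaftRadius + max(params@hAntMed, params@hAntLat) + margin,
            by = pitch)
  gz <- seq(-rMax - margin, 46, by = pitch)
  nx <- length(gx); ny <- length(gy); nz <- length(gz)
  P <- cbind(rep(gx, times = ny * nz),
             rep(rep(gy, each = nx), times = nz),
             rep(gz, each = nx * ny))
  vals <- implicitValue(params, P)
  ## boundary must be outside or the surface would be clipped open
  bIdx <- P[, 1L] %in% gx[c(1L, nx)] | P[, 2L] %in% gy[c(1L, ny)] | P[, 3L] %in% gz[c(1L, nz)]
  if (any(vals[bIdx] <= 0))
    stopGeometry("implicit femur reaches the sampling box boundary; enlarge margins")
  mt <- .marchingTets(vals, c(nx, ny, nz), gx, gy, gz)
  mesh <- TriMesh(mt$vertices, mt$faces)
  if (!meshIsClosed(mesh))
    stopGeometry("generated mesh is not watertight; retry with a finer voxel pitch")

  landmarks <- analyticLandmarks(params)
  feaMed <- cc$med; feaLat <- cc$lat
  steaMed <- landmark(landmarks, "med_epicondyle_sulcus")
  steaLat <- landmark(landmarks, "lat_epicondyle_prominence")

  mirrored <- params@side == "left"
  if (mirrored) {
    mw <- mirrorWorld(mesh, landmarks)     # flips side label to "left"
    mesh <- mw$mesh; landmarks <- mw$landmarks
    feaMed[1L] <- -feaMed[1L]; feaLat[1L] <- -feaLat[1L]
    steaMed[1L] <- -steaMed[1L]; steaLat[1L] <- -steaLat[1L]
  }

  if (pose == "random") {
    pr <- withSeed(params@seed + 3001L, {
      ax <- normalize(stats::rnorm(3L))
      list(R = rotationAbout(ax, stats::runif(1L, 0, 25)),
           t = stats::runif(3L, -30, 30))
    })
  } else pr <- list(R = diag(3), t = c(0, 0, 0))
  ar <- applyRigid(mesh, landmarks, pr$R, pr$t)
  xf <- function(p) drop(pr$R %*% p + pr$t)
  truth <- new("FemurTruth", landmarks = ar$landmarks,
               feaMed = xf(feaMed), feaLat = xf(feaLat),
               steaLat = xf(steaLat), steaMed = xf(steaMed),
               pose = pr, params = params)
  list(mesh = ar$mesh, landmarks = ar$landmarks, truth = truth)
}

## Map world points back to the canonical build coordinates recorded in a
## FemurTruth (inverse pose, then un-mirror); lets the implicit field serve
## as an oracle for posed meshes.
worldToBuild <- function(truth, points) {
  p <- if (is.null(dim(points))) matrix(points, 1L) else as.matrix(points)
  p0 <- sweep(p, 2L, truth@pose$t) %*% truth@pose$R   # R^-1 = t(R); p0 = (p - t) R
  if (truth@params@side == "left") p0[, 1L] <- -p0[, 1L]
  p0
}

#' Implicit-field value at world coordinates of a built femur
#'
#' Composes the inverse pose (and mirroring) recorded in the ground truth
#' with \code{\link{implicitValue}}; used as the independent oracle for
#' cross-section areas of posed meshes.
#'
#' @param truth a \linkS4class{FemurTruth}.
#' @param points n x 3 matrix of world coordinates, mm.
#' @return Numeric vector of field values.
#' @export
implicitValueWorld <- function(truth, points) {
  implicitValue(truth@params, worldToBuild(truth, points))
}

truthToList <- function(truth) {
  p <- truth@params
  list(params = list(mlWidth = p@mlWidth, apDepth = p@apDepth,
                     rCondMed = p@rCondMed, rCondLat = p@rCondLat,
                     shaftRadius = p@shaftRadius, shaftTaper = p@shaftTaper,
                     grooveDepth = p@grooveDepth, grooveApexAngle = p@grooveApexAngle,
                     hAntMed = p@hAntMed, hAntLat = p@hAntLat,
                     facetTaperSlope = p@facetTaperSlope,
                     epiOffMed = p@epiOffMed, epiOffLat = p@epiOffLat,
                     noiseAmplitude = p@noiseAmplitude,
                     noiseWavelength = p@noiseWavelength,
                     noiseBasis = p@noiseBasis,
                     side = p@side, archetype = p@archetype, seed = p@seed),
       pose = list(R = truth@pose$R, t = truth@pose$t),
       feaMed = truth@feaMed, feaLat = truth@feaLat,
       steaLat = truth@steaLat, steaMed = truth@steaMed)
}

#' Write / read femur ground truth (JSON)
#'
#' @param truth a \linkS4class{FemurTruth}.
#' @param path file path.
#' @return \code{writeTruth}: \code{path}, invisibly. \code{loadTruth}: a
#'   \linkS4class{FemurTruth} (its landmark slot is rebuilt from the
#'   parameters and pose).
#' @export
writeTruth <- function(truth, path) {
  obj <- truthToList(truth)
  lm <- truth@landmarks
  obj$landmarks <- c(lapply(LANDMARK_NAMES, function(k) unname(lm@points[k, ])),
                     list(lm@side))
  names(obj$landmarks) <- c(LANDMARK_NAMES, "side")
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = 10)
  invisible(path)
}

#' @rdname writeTruth
#' @export
loadTruth <- function(path) {
  obj <- jsonlite::fromJSON(path)
  pp <- obj$params
  params <- femurParams(mlWidth = pp$mlWidth,
                        rCondMed = pp$rCondMed, rCondLat = pp$rCondLat,
                        shaftRadius = pp$shaftRadius, shaftTaper = pp$shaftTaper,
                        grooveDepth = pp$grooveDepth, grooveApexAngle = pp$grooveApexAngle,
                        hAntMed = pp$hAntMed, hAntLat = pp$hAntLat,
                        facetTaperSlope = pp$facetTaperSlope,
                        epiOffMed = pp$epiOffMed, epiOffLat = pp$epiOffLat,
                        noiseAmplitude = pp$noiseAmplitude,
                        noiseWavelength = pp$noiseWavelength,
                        side = pp$side, archetype = pp$archetype, seed = pp$seed)
  params@noiseBasis <- matrix(as.numeric(pp$noiseBasis), nrow = nrow(pp$noiseBasis))
  lm <- LandmarkSet(obj$landmarks[LANDMARK_NAMES], obj$landmarks$side)
  new("FemurTruth", landmarks = lm,
      feaMed = as.numeric(obj$feaMed), feaLat = as.numeric(obj$feaLat),
      steaLat = as.numeric(obj$steaLat), steaMed = as.numeric(obj$steaMed),
      pose = list(R = matrix(as.numeric(obj$pose$R), 3L), t = as.numeric(obj$pose$t)),
      params = params)
}

#' Generate a synthetic cohort on disk
#'
#' Draws \code{nFemale} female-like and \code{nMale} male-like femurs with
#' per-knee seeds derived from \code{seed}, writes each mesh (binary STL),
#' landmark JSON and ground-truth JSON into \code{outDir}, and returns (and
#' writes) a manifest with columns \code{mesh, landmarks, truth, sex, seed}.
#' Fully reproducible: the same seed gives byte-identical landmark and truth
#' files.
#'
#' @param nFemale,nMale cohort sizes per archetype (each >= 1).
#' @param seed global integer seed.
#' @param outDir output directory (created if needed).
#' @param pitch voxel pitch, mm.
#' @param noiseAmplitude surface noise RMS amplitude, mm.
#' @return The manifest as a data.frame (also written to
#'   \code{manifest.csv}).
#' @export
generateCohort <- function(nFemale, nMale, seed, outDir, pitch = 0.8,
                           noiseAmplitude = 0.4) {
  if (nFemale < 1L || nMale < 1L)
    stop("cohort sizes must be >= 1 per archetype", call. = FALSE)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(outDir)) stop("cannot create output directory: ", outDir, call. = FALSE)
  n <- nFemale + nMale
  seeds <- withSeed(seed, sample.int(2147483646L, n))
  sex <- rep(c("female", "male"), c(nFemale, nMale))
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    params <- sampleFemurParams(if (sex[i] == "female") "female-like" else "male-like",
                                seed = seeds[i], noiseAmplitude = noiseAmplitude)
    fm <- buildFemur(params, pitch = pitch, pose = "random")
    id <- sprintf("knee_%03d", i)
    meshPath <- file.path(outDir, paste0(id, ".stl"))
    lmPath <- file.path(outDir, paste0(id, "_landmarks.json"))
    truthPath <- file.path(outDir, paste0(id, "_truth.json"))
    writeMesh(fm$mesh, meshPath)
    writeLandmarks(fm$landmarks, lmPath)
    writeTruth(fm$truth, truthPath)
    rows[[i]] <- data.frame(mesh = meshPath, landmarks = lmPath, truth = truthPath,
                            sex = sex[i], seed = seeds[i])
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(outDir, "manifest.csv"), row.names = FALSE)
  manifest
}
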