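# Shared fixtures. Built femurs are cached for the whole test run; every
# builder is deterministic, so caching never changes results.

femurCache <- new.env(parent = emptyenv())

cachedFemur <- function(key, builder) {
  if (is.null(femurCache[[key]])) femurCache[[key]] <- builder()
  femurCache[[key]]
}

## mirror-symmetric femur, canonical pose, noise off
symFemur <- function() {
  cachedFemur("sym", function() buildFemur(symmetricFemurParams(1), pitch = 0.8,
                                           pose = "none"))
}

## default (female-like means) femur with mild noise, canonical pose
defFemur <- function() {
  cachedFemur("def", function() buildFemur(femurParams(seed = 7, noiseAmplitude = 0.3,
                                                       archetype = "default"),
                                           pitch = 0.8, pose = "none"))
}

unitCubeMesh <- function() {
  v <- as.matrix(expand.grid(c(0, 1), c(0, 1), c(0, 1)))
  f <- rbind(c(1, 3, 2), c(2, 3, 4), c(5, 6, 7), c(6, 8, 7),
             c(1, 2, 5), c(2, 6, 5), c(3, 7, 4), c(4, 7, 8),
             c(1, 5, 3), c(3, 5, 7), c(2, 4, 6), c(4, 8, 6))
  TriMesh(v, f)
}

## implicit sphere mesh for closed-form section checks
sphereMesh <- function(r = 10, pitch = 0.25) {
  cachedFemur(sprintf("sphere_%g_%g", r, pitch), function() {
    g <- seq(-(r + 1), r + 1, by = pitch)
    P <- as.matrix(expand.grid(g, g, g))
    v <- sqrt(rowSums(P^2)) - r
    mt <- pianoSign:::.marchingTets(v, rep(length(g), 3L), g, g, g)
    TriMesh(mt$vertices, mt$faces)
  })
}

## axis-aligned toy landmarks (right knee, head at +z)
toyLandmarks <- function() {
  LandmarkSet(list(lat_epicondyle_prominence = c(-40, 0, 0),
                   med_epicondyle_sulcus = c(40, 0, 0),
                   trochlear_groove_deepest = c(0, 20, 0),
                   intercondylar_notch_highest = c(0, -10, 0),
                   femoral_head_center = c(0, 0, 400),
                   knee_center = c(0, 0, 0)), side = "right")
}

## minimal CutResult with constructed section polygons (planes are dummies)
toyCut <- function(anterior, distal, vStar = 0) {
  pl <- pianoSign:::makePlane(c(0, 0, 0), c(0, 1, 0), uDir = c(1, 0, 0))
  dp <- pianoSign:::makePlane(c(0, 0, 0), c(0, 0, 1), uDir = c(1, 0, 0))
  new("CutResult", distalPlane = dp, anteriorPlane = pl,
      anteriorSection = anterior, distalSection = distal,
      distalCutLine = rbind(c(0, vStar), c(1, 0)))
}

rectPoly <- function(u0, u1, v0, v1) {
  rbind(c(u0, v0), c(u1, v0), c(u1, v1), c(u0, v1))
}

## upper half-disc polygon of radius r centered at (uc, 0); the straight
## base edge closes the loop implicitly
halfDiscPoly <- function(uc, r, n = 200L) {
  th <- seq(0, pi, length.out = n)
  cbind(uc + r * cos(th), r * sin(th))
}

## ResectionProfile from explicit u/h vectors
makeProfile <- function(u, h, uDistal = range(u)) {
  new("ResectionProfile", u = u, h = h, uAnterior = range(u[!is.na(h)]),
      uDistal = uDistal)
}

## per-knee measurement records without meshes, for summary-table tests
fakeRecords <- function(nF, nM, meanF, meanM, sd = 0.05, seed = 1,
                        reference = "sTEA") {
  set.seed(seed)
  data.frame(
    LatL = 16, MedL = 10,
    MedL_LatL = c(rnorm(nF, meanF, sd), rnorm(nM, meanM, sd)),
    ML = c(rnorm(nF, 73, 3), rnorm(nM, 84, 4)),
    MpLp = 50, MpLp_ML_pct = 70, LD = 0.3, LD_ML_pct = 0.4,
    shape = sample(c("double_peak", "single_peak"), nF + nM, replace = TRUE),
    reference = reference,
    sex = rep(c("female", "male"), c(nF, nM)),
    knee = sprintf("k%03d", seq_len(nF + nM)), stringsAsFactors = FALSE)
}

## mesh-derived anterior-section area, mm^2
meshAnteriorArea <- function(cut) {
  sum(vapply(cut@anteriorSection, function(p) abs(polygonArea(p)), numeric(1)))
}

## independent oracle: area of {implicit field < 0} sampled on a regular grid
## within the anterior plane, clipped above the distal cutting line
anteriorAreaOracle <- function(fm, cut, step = 0.2) {
  pl <- cut@anteriorPlane
  ur <- range(unlist(lapply(cut@anteriorSection, function(p) p[, 1L]))) + c(-3, 3)
  vStar <- cut@distalCutLine[1L, 2L]
  vTop <- max(unlist(lapply(cut@anteriorSection, function(p) p[, 2L]))) + 3
  us <- seq(ur[1L], ur[2L], by = step)
  vs <- seq(vStar, vTop, by = step)
  G <- as.matrix(expand.grid(us, vs))
  Wcan <- sweep(outer(G[, 1L], pl@uDir) + outer(G[, 2L], pl@vDir), 2L, pl@point, "+")
  fr0 <- canonicalFrame(fm$landmarks)
  Worig <- pianoSign:::fromFrameCoords(Wcan, fr0)
  sum(implicitValueWorld(fm$truth, Worig) < 0) * step^2
}
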